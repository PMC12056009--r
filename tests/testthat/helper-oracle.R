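# Independent brute-force reference for the occupancy computation.
# Deliberately naive: loops read by read and position by position with
# substr(); used only on tiny inputs to cross-check the vectorized
# implementation.
oracle_occupancy <- function(aln, tx, offset = 12L, shift = 0L,
                             min_read_length = 27L, min_reads_per_gene = 1L) {
  aln <- as.data.frame(aln)
  tx <- as.data.frame(tx)
  rows <- list()
  for (smp in unique(aln$sample)) {
    a <- aln[aln$sample == smp, , drop = FALSE]
    # pass 1: per-gene usable reads and their triplets
    gene_reads <- list()
    for (i in seq_len(nrow(a))) {
      g <- match(a$transcript_id[i], tx$gene_id)
      if (is.na(g)) next
      if (a$read_length[i] < min_read_length) next
      site <- a$five_prime_pos[i] + offset
      if ((site - tx$cds_start[g]) %% 3 != 0) next
      ts <- site + shift
      if (ts < tx$cds_start[g] || ts + 3 > tx$cds_end[g] - 3) next
      trip <- substr(tx$sequence[g], ts + 1, ts + 3)
      gid <- tx$gene_id[g]
      gene_reads[[gid]] <- c(gene_reads[[gid]], trip)
    }
    gene_reads <- gene_reads[vapply(gene_reads, length, 0L) >=
                               min_reads_per_gene]
    if (length(gene_reads) == 0L) next
    # pass 2: observed and expected per triplet
    obs <- list(); expd <- list()
    for (gid in names(gene_reads)) {
      g <- match(gid, tx$gene_id)
      for (trip in gene_reads[[gid]]) {
        obs[[trip]] <- (if (is.null(obs[[trip]])) 0 else obs[[trip]]) + 1
      }
      # gene composition over valid triplet positions at this shift
      n_sense <- (tx$cds_end[g] - tx$cds_start[g]) / 3 - 1
      pos_trips <- character(0)
      for (i in 0:(n_sense - 1)) {
        ts <- tx$cds_start[g] + 3 * i + shift
        if (ts < tx$cds_start[g] || ts + 3 > tx$cds_end[g] - 3) next
        pos_trips <- c(pos_trips, substr(tx$sequence[g], ts + 1, ts + 3))
      }
      n_g <- length(gene_reads[[gid]])
      for (trip in unique(pos_trips)) {
        e <- n_g * sum(pos_trips == trip) / length(pos_trips)
        expd[[trip]] <- (if (is.null(expd[[trip]])) 0 else expd[[trip]]) + e
      }
    }
    for (trip in sort(unique(c(names(obs), names(expd))))) {
      e <- if (is.null(expd[[trip]])) 0 else expd[[trip]]
      o <- if (is.null(obs[[trip]])) 0 else obs[[trip]]
      if (e > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, codon = trip, observed = o, expected = e,
          occupancy = o / e, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$sample, out$codon), , drop = FALSE]
}
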