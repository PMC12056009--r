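#' Locate the ribosomal site of a footprint read
#'
#' The site nucleotide is `five_prime_pos + offset` (A-site: offset 12;
#' P-site: offset 15). Relative to the CDS, the read's frame is
#' `(site - cds_start) mod 3` and its codon index `(site - cds_start) div 3`
#' (0-based). Vectorized over reads.
#'
#' @param five_prime_pos 0-based 5'-end position(s) on the transcript.
#' @param cds_start,cds_end CDS interval (0-based, half-open).
#' @param offset Site offset in nt from the 5' end, in 11:16.
#' @return `data.frame` with `site`, `frame`, `codon_index`, and logical
#'   `in_cds` (`FALSE` when the site falls outside the CDS).
#' @export
#' @examples
#' assign_site(0, cds_start = 12, cds_end = 33, offset = 12)
assign_site <- function(five_prime_pos, cds_start, cds_end, offset = 12L) {
  if (!all(offset %in% 11:16)) stop("offset must be in 11..16")
  site <- as.integer(five_prime_pos) + as.integer(offset)
  rel <- site - as.integer(cds_start)
  in_cds <- site >= cds_start & site < cds_end
  data.frame(
    site = site,
    frame = ifelse(in_cds, rel %% 3L, NA_integer_),
    codon_index = ifelse(in_cds, rel %/% 3L, NA_integer_),
    in_cds = in_cds
  )
}

# Core counting engine shared by the in-frame and shifted analyses.
#
# Reads are kept when (i) read_length >= min_read_length, (ii) the
# *unshifted* site (five_prime_pos + offset) is in frame 0 of the CDS, and
# (iii) the trinucleotide starting at site + shift lies fully within the
# sense-codon region. The counted label is that trinucleotide: for
# shift = 0 it is the A-site (or P-site) codon; for shift = +/-1 it is the
# out-of-frame triplet one nucleotide away, whose occupancy carries the
# sampling noise of the data but no codon-level decoding signal.
site_counts <- function(aln, tx, offset = 12L, shift = 0L,
                        min_read_length = 27L, min_reads_per_gene = 64L) {
  stopifnot(nrow(tx) > 0L)
  offset <- as.integer(offset); shift <- as.integer(shift)
  dt <- data.table::as.data.table(aln)
  req <- c("sample", "transcript_id", "five_prime_pos", "read_length")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0L) stop("alignment table lacks columns: ",
                              paste(miss, collapse = ", "))
  dt <- dt[, req, with = FALSE]

  unknown <- setdiff(unique(dt$transcript_id), tx$gene_id)
  if (length(unknown) > 0L) {
    warning(length(unknown), " unknown transcript id(s) excluded: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    dt <- dt[!transcript_id %chin% unknown]
  }
  dt <- dt[read_length >= min_read_length]

  txi <- data.table::data.table(transcript_id = tx$gene_id,
                                cds_start = tx$cds_start,
                                cds_end = tx$cds_end)
  dt <- txi[dt, on = "transcript_id"]
  dt[, site := five_prime_pos + offset]
  # frame of the unshifted site defines the read set; the shift moves the
  # counted trinucleotide, not the frame filter
  dt <- dt[(site - cds_start) %% 3L == 0L]
  dt[, tri_start := site + shift]
  dt <- dt[tri_start >= cds_start & tri_start + 3L <= cds_end - 3L]

  # per-sample, per-gene totals and the gene coverage filter
  dt[, n_gene := .N, by = .(sample, transcript_id)]
  excluded <- unique(dt[n_gene < min_reads_per_gene,
                        .(sample, gene_id = transcript_id, n_inframe = n_gene)])
  dt <- dt[n_gene >= min_reads_per_gene]

  seq_lookup <- stats::setNames(tx$sequence, tx$gene_id)
  if (nrow(dt) > 0L) {
    dt[, codon := substring(seq_lookup[[.BY$transcript_id]],
                            tri_start + 1L, tri_start + 3L),
       by = transcript_id]
  } else {
    dt[, codon := character(0)]
  }
  counts <- dt[, .(count = .N), by = .(sample, gene_id = transcript_id, codon)]
  structure(
    list(counts = counts,
         gene_totals = dt[, .(n_reads = .N),
                          by = .(sample, gene_id = transcript_id)],
         excluded = excluded, offset = offset, shift = shift,
         min_read_length = min_read_length,
         min_reads_per_gene = min_reads_per_gene),
    class = "site_counts"
  )
}

#' Count in-frame ribosomal-site codons per gene
#'
#' Counts, per sample and gene, the reads whose site nucleotide
#' (`five_prime_pos + offset`) is in frame 0 of the CDS, keyed by the codon
#' at that site. Reads shorter than `min_read_length` (default 27 nt) are
#' discarded; genes with fewer than `min_reads_per_gene` in-frame reads are
#' excluded from downstream normalization (the exclusion list is attached).
#' Reads on unknown transcripts are excluded with a warning.
#'
#' @param aln Alignment table (`sample`, `transcript_id`, `five_prime_pos`,
#'   `read_length`).
#' @param tx A `transcript_set`.
#' @param offset Site offset (A = 12, P = 15).
#' @param min_read_length Minimum read length in nt, default 27.
#' @param min_reads_per_gene Minimum in-frame reads for a gene to enter the
#'   normalization, default 64.
#' @return A `site_counts` object: `counts` (sample, gene_id, codon, count),
#'   `gene_totals`, `excluded`.
#' @export
codon_counts <- function(aln, tx, offset = 12L, min_read_length = 27L,
                         min_reads_per_gene = 64L) {
  site_counts(aln, tx, offset = offset, shift = 0L,
              min_read_length = min_read_length,
              min_reads_per_gene = min_reads_per_gene)
}

#' Gene-level-normalized codon occupancy
#'
#' Pools counts over genes and normalizes by the within-gene codon
#' composition so that codon frequency biases cancel: for codon `c`,
#' observed `O_c = sum_g count_{g,c}` and expected
#' `E_c = sum_g N_g * e_{g,c}`, where `N_g` is gene g's counted reads and
#' `e_{g,c}` its codon frequency; the occupancy is `o_c = O_c / E_c`. Under
#' codon-indifferent elongation `o_c = 1` for every codon. Conservation
#' holds by construction: `sum_c O_c = sum_c E_c =` total reads used.
#'
#' @param counts A `site_counts` object from [codon_counts()].
#' @param tx The `transcript_set` the counts were computed against.
#' @return `data.table` (class `occupancy_profile`) with one row per
#'   (sample, codon): `sample`, `codon`, `observed`, `expected`,
#'   `occupancy`. Codons with `expected = 0` in a sample are omitted
#'   (undefined). Attributes: `offset`, `shift`, `n_genes_used`,
#'   `n_reads_used`.
#' @export
normalized_occupancy <- function(counts, tx) {
  stopifnot(inherits(counts, "site_counts"))
  if (nrow(counts$counts) == 0L) {
    stop("no genes pass the filters; cannot normalize")
  }
  trip <- shifted_triplets(tx, shift = counts$shift)
  comp <- data.table::rbindlist(lapply(names(trip), function(g) {
    tt <- trip[[g]]
    if (length(tt) == 0L) return(NULL)
    tab <- table(tt)
    data.table::data.table(gene_id = g, codon = names(tab),
                           e = as.numeric(tab) / length(tt))
  }))
  expd <- merge(counts$gene_totals, comp, by = "gene_id",
                allow.cartesian = TRUE)
  expected <- expd[, .(expected = sum(n_reads * e)), by = .(sample, codon)]
  observed <- counts$counts[, .(observed = sum(count)), by = .(sample, codon)]
  prof <- merge(expected, observed, by = c("sample", "codon"), all = TRUE)
  prof[is.na(observed), observed := 0]
  prof <- prof[!is.na(expected) & expected > 0]
  prof[, occupancy := observed / expected]
  data.table::setorder(prof, sample, codon)
  data.table::setcolorder(prof, c("sample", "codon", "observed", "expected",
                                  "occupancy"))
  data.table::setattr(prof, "class",
                      c("occupancy_profile", class(prof)))
  data.table::setattr(prof, "offset", counts$offset)
  data.table::setattr(prof, "shift", counts$shift)
  ng <- counts$gene_totals[, .(n = .N), by = sample]
  nr <- counts$gene_totals[, .(n = sum(n_reads)), by = sample]
  data.table::setattr(prof, "n_genes_used",
                      stats::setNames(ng$n, ng$sample))
  data.table::setattr(prof, "n_reads_used",
                      stats::setNames(nr$n, nr$sample))
  prof[]
}

#' Differential ribosome codon reading between conditions
#'
#' For each matched replicate pair, the per-codon signal is
#' `log2(o_c^treat / o_c^ctrl)`; the reported signal `s_c` is the
#' arithmetic mean across replicate pairs. Codons with undefined or
#' non-positive occupancy in any member of any pair are dropped from
#' testing and listed in `attr(, "dropped")`.
#'
#' @param profile An `occupancy_profile` covering all samples involved.
#' @param pairing `data.frame` with columns `treat` and `ctrl` giving
#'   matched sample labels, one row per replicate pair.
#' @return `data.table` (class `differential_signal`): `codon`,
#'   `mean_signal`, plus one `pair<k>` column per replicate pair.
#' @export
differential_signal <- function(profile, pairing) {
  pairing <- as.data.frame(pairing)
  stopifnot(all(c("treat", "ctrl") %in% names(pairing)), nrow(pairing) >= 1L)
  missing_samples <- setdiff(c(pairing$treat, pairing$ctrl),
                             unique(profile$sample))
  if (length(missing_samples) > 0L) {
    stop("profile lacks samples: ", paste(missing_samples, collapse = ", "))
  }
  occ <- data.table::as.data.table(profile)[, .(sample, codon, occupancy)]
  per_pair <- lapply(seq_len(nrow(pairing)), function(k) {
    t_occ <- occ[sample == pairing$treat[k], .(codon, o_t = occupancy)]
    c_occ <- occ[sample == pairing$ctrl[k], .(codon, o_c = occupancy)]
    m <- merge(t_occ, c_occ, by = "codon", all = TRUE)
    m[, value := ifelse(!is.na(o_t) & !is.na(o_c) & o_t > 0 & o_c > 0,
                        log2(o_t / o_c), NA_real_)]
    m[, .(codon, value)]
  })
  wide <- Reduce(function(a, b) merge(a, b, by = "codon", all = TRUE),
                 lapply(seq_along(per_pair), function(k) {
                   data.table::setnames(data.table::copy(per_pair[[k]]),
                                        "value", paste0("pair", k))
                 }))
  pair_cols <- paste0("pair", seq_len(nrow(pairing)))
  complete <- stats::complete.cases(wide[, pair_cols, with = FALSE])
  dropped <- wide$codon[!complete]
  res <- wide[complete]
  res[, mean_signal := rowMeans(.SD), .SDcols = pair_cols]
  data.table::setcolorder(res, c("codon", "mean_signal", pair_cols))
  data.table::setorder(res, codon)
  data.table::setattr(res, "class", c("differential_signal", class(res)))
  data.table::setattr(res, "dropped", dropped)
  data.table::setattr(res, "n_pairs", nrow(pairing))
  res[]
}

#' Restrict an analysis to a transcript subset
#'
#' Re-runs the occupancy pipeline on the alignments of a stated transcript
#' subset only (e.g. ribosomal-protein-like mRNAs), reproducing the
#' subsequence-level reanalysis of selected transcript classes.
#'
#' @param aln Alignment table.
#' @param tx A `transcript_set`.
#' @param transcript_ids Character vector of gene ids to keep.
#' @param pairing Optional pairing `data.frame`; when supplied the
#'   differential signal is returned alongside the profile.
#' @param ... Passed to [codon_counts()] (`offset`, `min_read_length`,
#'   `min_reads_per_gene`).
#' @return List with `profile` and (when `pairing` given) `signal`.
#' @export
subset_analysis <- function(aln, tx, transcript_ids, pairing = NULL, ...) {
  transcript_ids <- unique(transcript_ids)
  absent_tx <- setdiff(transcript_ids, tx$gene_id)
  if (length(absent_tx) > 0L) {
    stop("subset ids absent from transcript set: ",
         paste(utils::head(absent_tx, 5), collapse = ", "))
  }
  aln <- data.table::as.data.table(aln)
  absent_aln <- setdiff(transcript_ids, unique(aln$transcript_id))
  if (length(absent_aln) > 0L) {
    stop("subset ids absent from alignments: ",
         paste(utils::head(absent_aln, 5), collapse = ", "))
  }
  tx_sub <- tx[tx$gene_id %in% transcript_ids, , drop = FALSE]
  class(tx_sub) <- c("transcript_set", "data.frame")
  aln_sub <- aln[transcript_id %chin% transcript_ids]
  counts <- codon_counts(aln_sub, tx_sub, ...)
  profile <- normalized_occupancy(counts, tx_sub)
  out <- list(profile = profile)
  if (!is.null(pairing)) {
    out$signal <- differential_signal(profile, pairing)
  }
  out
}
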