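#' Construct a transcript set
#'
#' A transcript set is a plain `data.frame` with one row per gene carrying
#' the transcript sequence and the CDS interval in 0-based, half-open
#' transcript coordinates. One canonical CDS per gene is assumed; the CDS
#' includes the terminal stop codon, but all codon-level statistics exclude
#' it (61 sense codons only).
#'
#' @param gene_id Character vector of gene labels (unique).
#' @param sequence Character vector of transcript sequences (A/C/G/T).
#' @param cds_start,cds_end Integer vectors, 0-based half-open CDS interval.
#' @param group Optional character vector of group labels (default "all").
#' @return A `data.frame` of class `transcript_set` with columns `gene_id`,
#'   `sequence`, `cds_start`, `cds_end`, `group`.
#' @export
transcript_set <- function(gene_id, sequence, cds_start, cds_end,
                           group = "all") {
  tx <- data.frame(
    gene_id = as.character(gene_id),
    sequence = toupper(as.character(sequence)),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    group = rep_len(as.character(group), length(gene_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tx$gene_id)) stop("duplicate gene_id in transcript set")
  bad_len <- (tx$cds_end - tx$cds_start) %% 3L != 0L
  if (any(bad_len)) {
    stop("CDS length not divisible by 3 for: ",
         paste(tx$gene_id[bad_len], collapse = ", "))
  }
  if (any(tx$cds_end > nchar(tx$sequence)) || any(tx$cds_start < 0L)) {
    stop("CDS interval outside transcript bounds")
  }
  class(tx) <- c("transcript_set", "data.frame")
  tx
}

#' Extract CDS codons of each transcript
#'
#' @param tx A `transcript_set`.
#' @param include_stop Keep the terminal stop codon? Default `FALSE`.
#' @return Named list (by `gene_id`) of character vectors of codons.
#' @export
cds_codons <- function(tx, include_stop = FALSE) {
  out <- lapply(seq_len(nrow(tx)), function(i) {
    cds <- substr(tx$sequence[i], tx$cds_start[i] + 1L, tx$cds_end[i])
    cod <- split_codons(cds)
    n <- length(cod)
    if (!include_stop && n > 0L && cod[n] %in% .STOP_CODONS) cod <- cod[-n]
    cod
  })
  names(out) <- tx$gene_id
  out
}

# triplets read at positions cds_start + 3*i + shift, restricted so the
# trinucleotide lies fully within the sense-codon region of the CDS.
# shift = 0 reproduces the in-frame codons (terminal stop excluded).
shifted_triplets <- function(tx, shift = 0L) {
  shift <- as.integer(shift)
  out <- lapply(seq_len(nrow(tx)), function(i) {
    n_cod <- (tx$cds_end[i] - tx$cds_start[i]) %/% 3L - 1L # sense codons
    if (n_cod <= 0L) return(character(0))
    starts <- tx$cds_start[i] + 3L * (seq_len(n_cod) - 1L) + shift
    ok <- starts >= tx$cds_start[i] & (starts + 3L) <= (tx$cds_end[i] - 3L)
    starts <- starts[ok]
    substring(tx$sequence[i], starts + 1L, starts + 3L)
  })
  names(out) <- tx$gene_id
  out
}

#' Specify a gene group for the transcriptome generator
#'
#' A group is a family of genes sharing a codon-composition regime, e.g. a
#' bulk group with near-uniform usage and an "RP-like" group emulating the
#' strong AAA (lysine) enrichment of ribosomal protein mRNAs.
#'
#' Per-gene codon propensities are drawn from a Dirichlet distribution
#' centred on the normalized `codon_weights`, with concentration
#' `usage_dispersion`. This reproduces the between-gene codon-usage
#' heterogeneity of real transcriptomes (amino-acid and GC composition vary
#' between genes well beyond multinomial noise); set
#' `usage_dispersion = Inf` for pure multinomial sampling from the group
#' weights.
#'
#' @param name Group label.
#' @param n_genes Number of genes.
#' @param n_codons Integer range (length-2 vector, or a single value) of
#'   sense codons per gene; must be >= 8.
#' @param codon_weights Named numeric vector of relative sampling weights
#'   over the 61 sense codons. Missing codons get weight 1; non-negative,
#'   at least one positive.
#' @param usage_dispersion Dirichlet concentration for per-gene codon
#'   propensities (default 150); `Inf` disables per-gene heterogeneity.
#' @return A `gene_group` list.
#' @export
#' @examples
#' gene_group("RP-like", n_genes = 50, codon_weights = c(AAA = 10))
gene_group <- function(name, n_genes, n_codons = c(150L, 650L),
                       codon_weights = NULL, usage_dispersion = 150) {
  w <- stats::setNames(rep(1, length(.SENSE_CODONS)), .SENSE_CODONS)
  if (!is.null(codon_weights)) {
    bad <- setdiff(names(codon_weights), .SENSE_CODONS)
    if (length(bad) > 0L) {
      stop("codon_weights has non-sense codons: ", paste(bad, collapse = ", "))
    }
    w[names(codon_weights)] <- codon_weights
  }
  if (any(w < 0)) stop("codon weights must be non-negative")
  if (sum(w) <= 0) stop("codon weights sum to zero")
  n_codons <- as.integer(n_codons)
  if (length(n_codons) == 1L) n_codons <- c(n_codons, n_codons)
  if (min(n_codons) < 8L) stop("n_codons must be >= 8")
  structure(
    list(name = as.character(name), n_genes = as.integer(n_genes),
         n_codons = n_codons, codon_weights = w,
         usage_dispersion = usage_dispersion),
    class = "gene_group"
  )
}

#' Generate a synthetic transcriptome
#'
#' Draws, for each gene, a CDS of sense codons sampled from its group's
#' codon propensities, appends a random stop codon, and flanks the CDS with
#' random-nucleotide UTRs. A 5' UTR of at least 15 nt guarantees that every
#' CDS codon is reachable by the A-site (nt 12 from the 5' end) of a read
#' of length >= 27 even in the presence of 1-nt frame noise.
#'
#' @param groups A `gene_group` or list of them.
#' @param utr5_len,utr3_len UTR lengths in nt (defaults 36).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `transcript_set` (gene ids `<group>_g<serial>`).
#' @export
generate_transcriptome <- function(groups, utr5_len = 36L, utr3_len = 36L,
                                   seed = 1L) {
  if (inherits(groups, "gene_group")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, logical(1), "gene_group")))
  if (utr5_len < 15L) {
    warning("utr5_len < 15: codons near the CDS start are unobservable ",
            "by an A-site at nt offset 12 of a >=27-nt read")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  serial <- 0L
  rows <- lapply(groups, function(grp) {
    w <- grp$codon_weights
    p0 <- w / sum(w)
    out <- vector("list", grp$n_genes)
    for (j in seq_len(grp$n_genes)) {
      serial <<- serial + 1L
      n_c <- if (grp$n_codons[1] == grp$n_codons[2]) grp$n_codons[1] else
        sample(grp$n_codons[1]:grp$n_codons[2], 1L)
      p <- if (is.finite(grp$usage_dispersion)) {
        g <- stats::rgamma(length(p0), shape = grp$usage_dispersion * p0)
        if (sum(g) <= 0) p0 else g / sum(g)
      } else p0
      cod <- sample(.SENSE_CODONS, n_c, replace = TRUE, prob = p)
      cds <- paste0(paste(cod, collapse = ""), sample(.STOP_CODONS, 1L))
      utr5 <- paste(sample(bases, utr5_len, replace = TRUE), collapse = "")
      utr3 <- paste(sample(bases, utr3_len, replace = TRUE), collapse = "")
      out[[j]] <- data.frame(
        gene_id = sprintf("%s_g%04d", gsub("[^A-Za-z0-9]+", "", grp$name),
                          serial),
        sequence = paste0(utr5, cds, utr3),
        cds_start = utr5_len,
        cds_end = utr5_len + nchar(cds),
        group = grp$name,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  tx <- do.call(rbind, rows)
  transcript_set(tx$gene_id, tx$sequence, tx$cds_start, tx$cds_end, tx$group)
}

#' Write a transcript set to FASTA
#'
#' Headers carry `gene_id|cds_start|cds_end|group` with the CDS interval in
#' 0-based, half-open transcript coordinates.
#'
#' @param tx A `transcript_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(tx, path) {
  seqs <- Biostrings::DNAStringSet(tx$sequence)
  names(seqs) <- sprintf("%s|%d|%d|%s", tx$gene_id, tx$cds_start,
                         tx$cds_end, tx$group)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Load canonical CDS transcripts from FASTA
#'
#' Expects headers of the form `gene_id|cds_start|cds_end[|group]`
#' (0-based, half-open CDS interval). Records whose CDS length is not
#' divisible by 3 or whose sequence contains non-ACGT bases are skipped
#' with a warning; a header without parseable CDS coordinates is an error.
#'
#' @param path FASTA file.
#' @return A `transcript_set`; skipped gene ids are attached as
#'   `attr(, "skipped")`.
#' @export
load_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("no records in ", path)
    tx <- transcript_set(character(0), character(0), integer(0), integer(0))
    attr(tx, "skipped") <- character(0)
    return(tx)
  }
  parts <- strsplit(sub("\\s.*$", "", names(seqs)), "|", fixed = TRUE)
  n_parts <- lengths(parts)
  if (any(n_parts < 3L)) {
    stop("FASTA header missing cds_start/cds_end coordinates: ",
         paste(names(seqs)[n_parts < 3L][1:min(3, sum(n_parts < 3))],
               collapse = ", "))
  }
  gene_id <- vapply(parts, `[`, character(1), 1L)
  cds_start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  cds_end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(cds_start) || anyNA(cds_end)) {
    bad <- gene_id[is.na(cds_start) | is.na(cds_end)]
    stop("non-numeric CDS coordinates in header(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  group <- ifelse(n_parts >= 4L, vapply(parts, `[`, character(1), 4L), "all")
  sequence <- as.character(seqs)
  ok_len <- (cds_end - cds_start) %% 3L == 0L &
    cds_end <= nchar(sequence) & cds_start >= 0L
  cds_seq <- substr(sequence, cds_start + 1L, cds_end)
  ok_base <- !grepl("[^ACGT]", cds_seq)
  ok <- ok_len & ok_base
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped (CDS length/coordinates or ",
            "non-ACGT bases): ",
            paste(utils::head(gene_id[!ok], 5), collapse = ", "))
  }
  tx <- transcript_set(gene_id[ok], sequence[ok], cds_start[ok],
                       cds_end[ok], group[ok])
  attr(tx, "skipped") <- gene_id[!ok]
  tx
}
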