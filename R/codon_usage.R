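#' Per-transcript codon frequencies
#'
#' Frequency of each of the 61 sense codons within each transcript's CDS,
#' in percent of that transcript's codons (terminal stop excluded). Rows
#' sum to 100. Transcripts with zero sense codons are skipped with a
#' warning.
#'
#' @param tx A `transcript_set`.
#' @return Numeric matrix, genes x 61 codons, in percent
#'   (class `codon_usage`).
#' @export
codon_frequencies <- function(tx) {
  stopifnot(nrow(tx) >= 1L)
  codons <- cds_codons(tx)
  n_cod <- lengths(codons)
  if (any(n_cod == 0L)) {
    warning("transcript(s) with no sense codons skipped: ",
            paste(names(codons)[n_cod == 0L], collapse = ", "))
    codons <- codons[n_cod > 0L]
  }
  u <- t(vapply(codons, function(cc) {
    tab <- tabulate(factor(cc, levels = .SENSE_CODONS),
                    nbins = length(.SENSE_CODONS))
    100 * tab / length(cc)
  }, numeric(length(.SENSE_CODONS))))
  colnames(u) <- .SENSE_CODONS
  rownames(u) <- names(codons)
  class(u) <- c("codon_usage", "matrix", "array")
  u
}

#' Transcriptome-average reference codon frequencies
#'
#' The reference is the unweighted mean over transcripts of the
#' per-transcript codon frequencies (each gene counts once, regardless of
#' CDS length). Which transcripts form the universe (all annotated, or only
#' those detected in a proteome) is the caller's choice of `u` rows.
#'
#' @param u Matrix from [codon_frequencies()] (>= 2 transcripts for a
#'   meaningful reference).
#' @return Named numeric vector of length 61, summing to 100.
#' @export
reference_frequencies <- function(u) {
  if (nrow(u) < 2L) {
    warning("reference computed from a single transcript; all deviations ",
            "will be zero")
  }
  colMeans(u)
}

#' Codon-usage deviation from the transcriptome average
#'
#' Per-codon deviation `d_{t,c} = u_{t,c} - r_c` in percentage points, plus
#' codon-set aggregates (sum of member deviations). By construction
#' deviations sum to zero within each transcript, so the non-VAA set
#' deviation is exactly the negative of the VAA deviation.
#'
#' @param u Matrix from [codon_frequencies()].
#' @param reference Reference vector; computed from `u` via
#'   [reference_frequencies()] when `NULL`. Pass a reference computed on a
#'   different transcript universe to decouple the two.
#' @param sets Named list of codon sets (default [default_codon_sets()]).
#' @return List: `deviation` (genes x 61 matrix, percentage points),
#'   `set_deviation` (genes x sets matrix), `reference`.
#' @export
usage_deviation <- function(u, reference = NULL,
                            sets = default_codon_sets()) {
  if (is.null(reference)) reference <- reference_frequencies(u)
  stopifnot(identical(names(reference), colnames(u)))
  for (s in names(sets)) {
    bad <- setdiff(sets[[s]], .SENSE_CODONS)
    if (length(bad) > 0L) {
      stop("codon set '", s, "' contains non-sense codons: ",
           paste(bad, collapse = ", "))
    }
  }
  d <- sweep(unclass(u), 2L, reference, `-`)
  sd_mat <- vapply(sets, function(members) {
    rowSums(d[, members, drop = FALSE])
  }, numeric(nrow(d)))
  if (is.null(dim(sd_mat))) {  # single gene
    sd_mat <- matrix(sd_mat, nrow = 1L, dimnames = list(rownames(d),
                                                        names(sets)))
  }
  list(deviation = d, set_deviation = sd_mat, reference = reference)
}
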