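#' Empirical null from 1-nt out-of-frame shifts
#'
#' Builds the background distribution used to judge differential codon
#' reading signals: the full differential pipeline is recomputed with the
#' counted trinucleotide shifted by -1 and +1 nt from the analyzed codon.
#' Those trinucleotides straddle codon boundaries, so their occupancy
#' changes carry the technical and sampling variability of the data but no
#' codon-level decoding signal. The per-codon mean signals at both shifts,
#' over the 61 sense-codon trinucleotides, are pooled into one background
#' per dataset; its mean and standard deviation parameterize the Z-test.
#'
#' @param aln Alignment table covering all samples in `pairing`.
#' @param tx A `transcript_set`.
#' @param pairing `data.frame` with `treat`/`ctrl` sample columns.
#' @param offset Site offset of the in-frame analysis (default 12).
#' @param shifts Integer shifts defining the background (default `c(-1, 1)`).
#' @param min_background Minimum number of defined background values
#'   required to test (default 30).
#' @param ... Passed to [codon_counts()].
#' @return A `shift_null` object: `background` (`data.table`: shift, codon,
#'   value), `mu`, `sd` (denominator n-1), `n`, and `normality`
#'   (see [normality_check()]).
#' @export
shift_null <- function(aln, tx, pairing, offset = 12L, shifts = c(-1L, 1L),
                       min_background = 30L, ...) {
  stopifnot(length(shifts) >= 1L, all(shifts != 0L))
  bg <- data.table::rbindlist(lapply(as.integer(shifts), function(sh) {
    counts <- site_counts(aln, tx, offset = offset, shift = sh, ...)
    prof <- normalized_occupancy(counts, tx)
    sig <- differential_signal(prof, pairing)
    data.table::data.table(shift = sh, codon = sig$codon,
                           value = sig$mean_signal)
  }))
  bg <- bg[codon %chin% .SENSE_CODONS & is.finite(value)]
  if (nrow(bg) < min_background) {
    stop("only ", nrow(bg), " defined background values (< ",
         min_background, "); refusing to test")
  }
  sd_b <- stats::sd(bg$value)
  if (!is.finite(sd_b) || sd_b == 0) {
    stop("degenerate background: zero variance (treat and ctrl identical?)")
  }
  nrm <- normality_check(bg$value)
  structure(
    list(background = bg[], mu = mean(bg$value), sd = sd_b, n = nrow(bg),
         offset = offset, shifts = as.integer(shifts), normality = nrm),
    class = "shift_null"
  )
}

#' Normality diagnostics for a background distribution
#'
#' The Z-test assumes an approximately normal background; this reports the
#' Anderson-Darling and Shapiro-Wilk statistics and the q-q points
#' (theoretical normal quantiles vs standardized empirical quantiles) for
#' inspection. Diagnostics are advisory: downstream testing proceeds but is
#' marked "non-normal background" when the Shapiro-Wilk p-value falls below
#' the chosen threshold.
#'
#' @param b Numeric vector of background values, length >= 8, non-constant.
#' @return A `normality_check` list: `ad_stat`, `ad_p`, `sw_stat`, `sw_p`,
#'   `qq` (`data.frame`: theoretical, empirical), `n`.
#' @export
normality_check <- function(b) {
  b <- b[is.finite(b)]
  if (length(b) < 8L) stop("need >= 8 background values, got ", length(b))
  if (stats::sd(b) == 0) stop("degenerate background: constant values")
  ad <- nortest::ad.test(b)
  sw <- stats::shapiro.test(b)
  z <- sort((b - mean(b)) / stats::sd(b))
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(b))),
                   empirical = z)
  structure(list(ad_stat = unname(ad$statistic), ad_p = ad$p.value,
                 sw_stat = unname(sw$statistic), sw_p = sw$p.value,
                 qq = qq, n = length(b)),
            class = "normality_check")
}

#' Z-tests of in-frame signals against the shift null
#'
#' Each codon's in-frame differential signal is standardized against the
#' background mean and standard deviation, `z_c = (s_c - mu_B) / sd_B`, and
#' tested one-sided for an occupancy increase (upper tail of the standard
#' normal) by default. Raw p-values are reported; a Benjamini-Hochberg
#' column is provided for convenience but no adjustment is applied to the
#' flags.
#'
#' @param signal A `differential_signal` table.
#' @param null A `shift_null` object.
#' @param alpha Flagging level (default 0.05).
#' @param two_sided Use a two-sided alternative (default `FALSE`).
#' @param sw_threshold Shapiro-Wilk p-value below which results are marked
#'   as having a non-normal background (default 0.01).
#' @return `data.table`: `codon`, `signal`, `z`, `p`, `p_bh`,
#'   `flagged_increase`. Attributes `nonnormal_background` (logical) and
#'   `null` (the `shift_null` used).
#' @export
z_test <- function(signal, null, alpha = 0.05, two_sided = FALSE,
                   sw_threshold = 0.01) {
  stopifnot(inherits(null, "shift_null"))
  if (!is.finite(null$sd) || null$sd <= 0) stop("degenerate background")
  res <- data.table::data.table(codon = signal$codon,
                                signal = signal$mean_signal)
  skipped <- res[!is.finite(signal), codon]
  if (length(skipped) > 0L) {
    warning("codon(s) with undefined signal skipped: ",
            paste(skipped, collapse = ", "))
    res <- res[is.finite(signal)]
  }
  res[, z := (signal - null$mu) / null$sd]
  if (two_sided) {
    res[, p := 2 * stats::pnorm(abs(z), lower.tail = FALSE)]
  } else {
    res[, p := stats::pnorm(z, lower.tail = FALSE)]
  }
  res[, p_bh := stats::p.adjust(p, method = "BH")]
  res[, flagged_increase := p < alpha & z > 0]
  nonnormal <- is.finite(null$normality$sw_p) &&
    null$normality$sw_p < sw_threshold
  if (nonnormal) {
    warning("background fails Shapiro-Wilk at p < ", sw_threshold,
            "; Z-test p-values may be miscalibrated")
  }
  data.table::setattr(res, "nonnormal_background", nonnormal)
  data.table::setattr(res, "skipped", skipped)
  data.table::setattr(res, "null", null)
  res[]
}

#' Full differential codon reading pipeline
#'
#' Convenience wrapper chaining [codon_counts()], [normalized_occupancy()],
#' [differential_signal()], [shift_null()] and [z_test()] on one dataset,
#' optionally restricted to a transcript subset.
#'
#' @param aln Alignment table.
#' @param tx A `transcript_set`.
#' @param pairing `data.frame` with `treat`/`ctrl` sample columns.
#' @param offset Site offset (default 12, the A-site).
#' @param subset Optional character vector of transcript ids.
#' @param alpha,two_sided,sw_threshold Passed to [z_test()].
#' @param ... Passed to [codon_counts()] / [shift_null()]
#'   (`min_read_length`, `min_reads_per_gene`).
#' @return List: `profile`, `signal`, `null`, `tests`.
#' @export
run_diricore <- function(aln, tx, pairing, offset = 12L, subset = NULL,
                         alpha = 0.05, two_sided = FALSE,
                         sw_threshold = 0.01, ...) {
  aln <- data.table::as.data.table(aln)
  if (!is.null(subset)) {
    subset <- unique(subset)
    absent <- setdiff(subset, tx$gene_id)
    if (length(absent) > 0L) {
      stop("subset ids absent from transcript set: ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
    absent_aln <- setdiff(subset, unique(aln$transcript_id))
    if (length(absent_aln) > 0L) {
      stop("subset ids absent from alignments: ",
           paste(utils::head(absent_aln, 5), collapse = ", "))
    }
    tx <- tx[tx$gene_id %in% subset, , drop = FALSE]
    class(tx) <- c("transcript_set", "data.frame")
    aln <- aln[transcript_id %chin% subset]
  }
  counts <- codon_counts(aln, tx, offset = offset, ...)
  profile <- normalized_occupancy(counts, tx)
  signal <- differential_signal(profile, pairing)
  null <- shift_null(aln, tx, pairing, offset = offset, ...)
  tests <- z_test(signal, null, alpha = alpha, two_sided = two_sided,
                  sw_threshold = sw_threshold)
  list(profile = profile, signal = signal, null = null, tests = tests)
}
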