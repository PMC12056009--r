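#' Center nascent-proteome ratios on the whole-lysate normalizer
#'
#' Pulsed-SILAC ratios of newly synthesized proteins confound per-gene
#' regulation with the overall synthesis rate difference between
#' conditions. The whole-lysate median log2 ratio estimates that overall
#' difference, and subtracting it centers the nascent-proteome
#' distribution: `centered_log2fc = log2_ratio - lysate_median`.
#'
#' @param table `data.frame` with columns `gene_id`, `replicate`,
#'   `log2_ratio`.
#' @param lysate_median Finite log2 normalizer value.
#' @return `data.table` with an added `centered_log2fc` column.
#' @export
center_nsp <- function(table, lysate_median) {
  if (length(lysate_median) != 1L || !is.finite(lysate_median)) {
    stop("lysate_median must be a single finite value")
  }
  tab <- data.table::as.data.table(table)
  stopifnot(all(c("gene_id", "log2_ratio") %in% names(tab)))
  tab[, centered_log2fc := log2_ratio - lysate_median]
  tab[]
}

#' Decile ranks of per-gene log2 fold changes
#'
#' Replicates are aggregated per gene (unweighted mean of
#' `centered_log2fc`), genes are sorted ascending, and equal-count bins are
#' assigned: decile 1 holds the ~10% most decreased genes. Ties are broken
#' by stable input order; bin sizes differ by at most 1.
#'
#' @param table Output of [center_nsp()] (needs `gene_id`,
#'   `centered_log2fc`).
#' @param n_bins Number of bins (default 10).
#' @return `data.table`: `gene_id`, `log2fc` (replicate-averaged),
#'   `decile`.
#' @export
decile_ranks <- function(table, n_bins = 10L) {
  tab <- data.table::as.data.table(table)
  stopifnot(all(c("gene_id", "centered_log2fc") %in% names(tab)))
  per_gene <- tab[is.finite(centered_log2fc),
                  .(log2fc = mean(centered_log2fc)), by = gene_id]
  n <- nrow(per_gene)
  if (n < n_bins) stop("need at least ", n_bins, " genes with finite values")
  ord <- order(per_gene$log2fc)  # radix sort: stable in input order on ties
  res <- per_gene[ord]
  res[, decile := ceiling(seq_len(n) * n_bins / n)]
  res[]
}

#' Codon-usage deviation by fold-change decile
#'
#' Summarizes a codon-set usage deviation within each log2FC decile
#' (median, interquartile range) and tests each decile's deviations against
#' all other quantified genes with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction). The global median over all
#' quantified genes is attached for reference.
#'
#' @param deciles Output of [decile_ranks()].
#' @param deviation Named numeric vector of per-gene codon-set deviations
#'   (percentage points), names = gene ids. Genes missing a deviation are
#'   dropped (inner join) and reported via `attr(, "unmatched")`.
#' @return `data.table`: `decile`, `n`, `median_dev`, `q25`, `q75`, `p`
#'   (NA when `n < 3`). Attributes: `global_median`, `unmatched`.
#' @export
decile_deviation_summary <- function(deciles, deviation) {
  stopifnot(!is.null(names(deviation)))
  dd <- data.table::as.data.table(deciles)
  dd[, dev := deviation[gene_id]]
  unmatched <- dd[is.na(dev), gene_id]
  if (length(unmatched) > 0L) {
    warning(length(unmatched), " gene(s) without deviation dropped")
    dd <- dd[!is.na(dev)]
  }
  global_median <- stats::median(dd$dev)
  res <- dd[, {
    rest <- dd$dev[dd$decile != .BY$decile]
    p <- if (.N >= 3L && length(rest) >= 3L) {
      stats::wilcox.test(dev, rest, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value
    } else NA_real_
    .(n = .N, median_dev = stats::median(dev),
      q25 = unname(stats::quantile(dev, 0.25)),
      q75 = unname(stats::quantile(dev, 0.75)), p = p)
  }, by = decile]
  data.table::setorder(res, decile)
  data.table::setattr(res, "global_median", global_median)
  data.table::setattr(res, "unmatched", unmatched)
  res[]
}

#' Gene-set level fold-change and deviation summary
#'
#' For each gene set (e.g. a ribosomal-protein-like group), reports the
#' median log2FC and median codon-set deviation of its quantified members,
#' with a two-sided rank-sum test of the set's log2FC against all
#' quantified genes.
#'
#' @param gene_sets Named list of character vectors of gene ids, or a
#'   two-column `data.frame` (`set`, `gene_id`).
#' @param deciles Output of [decile_ranks()].
#' @param deviation Named numeric vector of per-gene deviations (optional;
#'   `median_dev` is NA when absent for a set).
#' @return `data.table`: `set`, `n`, `median_log2fc`, `median_dev`, `p`
#'   (NA when `n < 3`). Sets with no quantified members are reported with
#'   `n = 0` and skipped from testing.
#' @export
set_level_summary <- function(gene_sets, deciles, deviation = NULL) {
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("set", "gene_id") %in% names(gene_sets)))
    gene_sets <- split(gene_sets$gene_id, gene_sets$set)
  }
  dd <- data.table::as.data.table(deciles)
  res <- data.table::rbindlist(lapply(names(gene_sets), function(s) {
    members <- dd[gene_id %chin% gene_sets[[s]]]
    if (nrow(members) == 0L) {
      return(data.table::data.table(set = s, n = 0L,
                                    median_log2fc = NA_real_,
                                    median_dev = NA_real_, p = NA_real_))
    }
    p <- if (nrow(members) >= 3L) {
      stats::wilcox.test(members$log2fc, dd$log2fc,
                         alternative = "two.sided", exact = FALSE,
                         correct = TRUE)$p.value
    } else NA_real_
    md <- if (!is.null(deviation)) {
      dv <- deviation[members$gene_id]
      if (all(is.na(dv))) NA_real_ else stats::median(dv, na.rm = TRUE)
    } else NA_real_
    data.table::data.table(set = s, n = nrow(members),
                           median_log2fc = stats::median(members$log2fc),
                           median_dev = md, p = p)
  }))
  res[]
}
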