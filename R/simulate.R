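#' Specify a ribosome dwell model
#'
#' Describes the codon-dependent A-site dwell of one condition: footprint
#' reads are placed so that their A-site codon is sampled within each gene
#' proportionally to `dwell[codon]`. A `frame_noise` fraction of reads has
#' its recorded 5' end displaced by +/-1 nt (equiprobable), emulating
#' imprecise nuclease trimming; those reads fall out of frame and are
#' excluded by the in-frame analysis.
#'
#' @param dwell Named numeric vector of relative dwell weights per codon
#'   (missing codons get 1); all weights > 0.
#' @param frame_noise Fraction of reads with a +/-1 nt offset error, in
#'   `[0, 0.5)`. Default 0.1.
#' @param read_lengths Integer vector of candidate read lengths, all >= 27
#'   (fragments below 27 nt are discarded upstream). Default 27:33.
#' @param read_length_prob Probabilities for `read_lengths` (default
#'   uniform).
#' @return A `dwell_model` list.
#' @export
#' @examples
#' dwell_model(dwell = c(AAA = 2))  # doubled dwell at AAA
dwell_model <- function(dwell = NULL, frame_noise = 0.1,
                        read_lengths = 27:33, read_length_prob = NULL) {
  d <- stats::setNames(rep(1, length(.SENSE_CODONS)), .SENSE_CODONS)
  if (!is.null(dwell)) {
    bad <- setdiff(names(dwell), .SENSE_CODONS)
    if (length(bad) > 0L) stop("dwell has non-sense codons: ",
                               paste(bad, collapse = ", "))
    d[names(dwell)] <- dwell
  }
  if (any(d <= 0)) stop("dwell weights must be positive")
  if (frame_noise < 0 || frame_noise >= 0.5) {
    stop("frame_noise must be in [0, 0.5)")
  }
  read_lengths <- as.integer(read_lengths)
  if (any(read_lengths < 27L)) stop("read lengths must be >= 27 nt")
  if (is.null(read_length_prob)) {
    read_length_prob <- rep(1 / length(read_lengths), length(read_lengths))
  }
  stopifnot(length(read_length_prob) == length(read_lengths))
  structure(list(dwell = d, frame_noise = frame_noise,
                 read_lengths = read_lengths,
                 read_length_prob = read_length_prob),
            class = "dwell_model")
}

#' Simulate ribosome footprint alignments
#'
#' For each condition and replicate, places `per_gene_depth` reads on every
#' gene: the A-site codon (nt 12-14 from the recorded 5' end) is sampled
#' among the gene's sense codons proportionally to the condition's dwell
#' weights; a `frame_noise` fraction of 5' ends is then displaced by +/-1
#' nt; read lengths are drawn from the model's length distribution (and
#' truncated if a read would overrun the transcript end). Replicates are
#' independent draws.
#'
#' @param tx A `transcript_set`.
#' @param conditions Named list of `dwell_model`s, one per condition.
#' @param per_gene_depth Reads per gene per sample.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @param a_site_offset Nucleotide offset of the A-site from the 5' end
#'   (default 12).
#' @return `data.table` with columns `sample`, `condition`, `replicate`,
#'   `transcript_id`, `five_prime_pos` (0-based), `read_length`. Sample
#'   labels are `<condition>_rep<k>`. The ground-truth dwell tables are
#'   attached as `attr(, "truth")` (a `data.table`: condition, codon,
#'   dwell).
#' @export
simulate_footprints <- function(tx, conditions, per_gene_depth,
                                n_replicates = 1L, seed = 1L,
                                a_site_offset = 12L) {
  stopifnot(nrow(tx) > 0L, !is.null(names(conditions)),
            all(vapply(conditions, inherits, logical(1), "dwell_model")))
  set.seed(seed)
  per_gene_depth <- as.integer(per_gene_depth)
  codons_by_gene <- cds_codons(tx)
  tx_len <- nchar(tx$sequence)
  out <- vector("list", length(conditions) * n_replicates)
  k <- 0L
  for (cond in names(conditions)) {
    model <- conditions[[cond]]
    # per-gene A-site sampling probabilities under this condition
    probs <- lapply(codons_by_gene, function(cc) {
      w <- model$dwell[cc]
      w / sum(w)
    })
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      if (per_gene_depth == 0L) {
        out[[k]] <- data.table::data.table(
          sample = character(0), condition = character(0),
          replicate = integer(0), transcript_id = character(0),
          five_prime_pos = integer(0), read_length = integer(0))
        next
      }
      per_gene <- vector("list", nrow(tx))
      for (g in seq_len(nrow(tx))) {
        n_cod <- length(codons_by_gene[[g]])
        if (n_cod == 0L) stop("gene ", tx$gene_id[g], " has no sense codons")
        idx <- sample.int(n_cod, per_gene_depth, replace = TRUE,
                          prob = probs[[g]])
        pos <- tx$cds_start[g] + 3L * (idx - 1L) - a_site_offset
        fn <- model$frame_noise
        if (fn > 0) {
          pos <- pos + sample(c(-1L, 0L, 1L), per_gene_depth, replace = TRUE,
                              prob = c(fn / 2, 1 - fn, fn / 2))
        }
        len <- model$read_lengths[
          sample.int(length(model$read_lengths), per_gene_depth,
                     replace = TRUE, prob = model$read_length_prob)]
        len <- pmin(len, tx_len[g] - pos)
        if (any(pos < 0L)) stop("read 5' end before transcript start; ",
                                "increase utr5_len (>= 15 required)")
        per_gene[[g]] <- data.table::data.table(
          transcript_id = tx$gene_id[g], five_prime_pos = pos,
          read_length = len)
      }
      dt <- data.table::rbindlist(per_gene)
      dt[, `:=`(sample = paste0(cond, "_rep", rep_i), condition = cond,
                replicate = rep_i)]
      out[[k]] <- dt
    }
  }
  aln <- data.table::rbindlist(out)
  data.table::setcolorder(aln, c("sample", "condition", "replicate",
                                 "transcript_id", "five_prime_pos",
                                 "read_length"))
  truth <- data.table::rbindlist(lapply(names(conditions), function(cond) {
    data.table::data.table(condition = cond, codon = .SENSE_CODONS,
                           dwell = unname(conditions[[cond]]$dwell))
  }))
  attr(aln, "truth") <- truth
  aln[]
}

#' Specify a proteome effect model
#'
#' Generates per-gene log2 synthesis fold changes as a linear function of
#' codon-usage deviation:
#' `log2FC = global_offset + sum_s beta[s] * deviation_s + Normal(0, sigma)`,
#' where `deviation_s` is the gene's codon-set usage deviation in
#' percentage points. The `global_offset` emulates an overall change in
#' synthesis shared by all genes (what the whole-lysate normalizer removes).
#'
#' @param beta Named numeric vector of slopes (log2 units per percentage
#'   point) keyed by codon-set name (see [default_codon_sets()]).
#' @param sigma Residual standard deviation of log2FC, >= 0.
#' @param global_offset Additive log2 shift shared by all genes.
#' @return A `proteome_effect` list.
#' @export
#' @examples
#' proteome_effect(beta = c(AAA = -0.05), sigma = 0.1, global_offset = -0.3)
proteome_effect <- function(beta = numeric(0), sigma = 0.1,
                            global_offset = 0) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(beta = beta, sigma = sigma,
                 global_offset = global_offset),
            class = "proteome_effect")
}

#' Simulate a nascent-proteome SILAC table
#'
#' Per-gene codon-set usage deviations are computed from the transcript set
#' (via [codon_frequencies()] and [usage_deviation()]); each replicate's
#' log2 SILAC ratio is the linear effect-model prediction plus independent
#' Gaussian noise. A whole-lysate normalizer is simulated alongside as the
#' median of per-gene lysate ratios `Normal(global_offset, sigma)`, so it
#' equals the global offset up to sampling noise.
#'
#' @param tx A `transcript_set`.
#' @param effect A `proteome_effect`.
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @param sets Codon sets referenced by `effect$beta`
#'   (default [default_codon_sets()]).
#' @return List with `table` (`data.table`: gene_id, replicate,
#'   log2_ratio), `lysate_median` (numeric), and `truth` (the effect model
#'   plus the per-gene expected log2FC and the deviations used).
#' @export
simulate_proteome <- function(tx, effect, n_replicates = 3L, seed = 1L,
                              sets = default_codon_sets()) {
  stopifnot(inherits(effect, "proteome_effect"))
  set.seed(seed)
  u <- codon_frequencies(tx)
  dev <- usage_deviation(u, sets = sets)
  mu <- rep(effect$global_offset, nrow(tx))
  if (length(effect$beta) > 0L) {
    missing_sets <- setdiff(names(effect$beta), colnames(dev$set_deviation))
    if (length(missing_sets) > 0L) {
      stop("beta refers to unknown codon sets: ",
           paste(missing_sets, collapse = ", "))
    }
    for (s in names(effect$beta)) {
      mu <- mu + effect$beta[[s]] * dev$set_deviation[, s]
    }
  }
  tab <- data.table::CJ(gene_id = tx$gene_id, replicate = seq_len(n_replicates),
                        sorted = FALSE)
  tab[, log2_ratio := rep(mu, each = n_replicates) +
        stats::rnorm(.N, 0, effect$sigma)]
  lysate <- stats::median(effect$global_offset +
                            stats::rnorm(nrow(tx), 0, effect$sigma))
  list(table = tab[], lysate_median = lysate,
       truth = list(beta = effect$beta, sigma = effect$sigma,
                    global_offset = effect$global_offset,
                    expected_log2fc = stats::setNames(mu, tx$gene_id),
                    set_deviation = dev$set_deviation))
}
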