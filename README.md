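# ribocodon

Codon-level analysis of translational control for ribosome profiling and
nascent-proteome data, built around the biology of wobble-uridine (U34)
tRNA modification: the mcm5s2 modification of U34 enhances decoding of the
VAA codons AAA (Lys), CAA (Gln) and GAA (Glu), and its loss slows
elongation at those codons and depresses synthesis of VAA-rich proteins
(most prominently the AAA-rich ribosomal proteins). The package is for
computational biologists who have footprint alignments in transcript
coordinates and per-gene proteome fold changes and want the codon-level
statistics connecting the two.

## What it computes

**Differential ribosome codon reading.** With frame-0 A-site counts
(site nucleotide = 5′ end + 12; P-site + 15) pooled over genes, occupancy
is gene-level normalized,

    O_c = Σ_g n_{g,c},   E_c = Σ_g N_g · e_{g,c},   o_c = O_c / E_c,

where `e_{g,c}` is gene g's codon frequency, so codon composition biases
cancel exactly (`o_c = 1` for every codon under codon-indifferent
elongation). The per-codon signal between conditions is
`s_c = mean over replicate pairs of log2(o_c^treat / o_c^ctrl)`.

**Shift-null significance.** A background distribution B is built by
re-running the identical pipeline with the counted trinucleotide shifted
±1 nt off the codon (the same reads, read out across codon boundaries);
in-frame signals are tested as `z_c = (s_c − mean B) / sd B` with one-sided
upper-tail normal p-values, plus Anderson–Darling / Shapiro–Wilk normality
diagnostics of B.

**Codon usage deviation.** Per-transcript codon frequencies in % (stop
excluded), a transcriptome-average reference (unweighted mean over
transcripts), deviation `d_{t,c} = u_{t,c} − r_c` in percentage points, and
the AAA/CAA/GAA/VAA/non-VAA set aggregates.

**Proteome correlation.** Centering of nascent-proteome SILAC ratios on the
whole-lysate median, decile ranks of replicate-averaged log2FC (decile 1 =
most decreased), per-decile deviation medians with two-sided Wilcoxon
rank-sum tests, and gene-set level summaries.

**Synthetic data with ground truth.** Transcriptome, footprint and proteome
generators with codon-dependent dwell, frame noise, replicate structure and
deviation-linear synthesis effects, used by the packaged calibration and
recovery checks.

## Worked example

An AAA-enriched "RP-like" gene group, doubled AAA dwell in the treated
condition, and a proteome in which log2FC decreases with AAA usage
deviation:

```r
library(ribocodon)

tx <- generate_transcriptome(list(
  gene_group("bulk", 240),
  gene_group("RP-like", 60, codon_weights = c(AAA = 10))), seed = 1)

aln <- simulate_footprints(
  tx, list(ctrl = dwell_model(), treat = dwell_model(dwell = c(AAA = 2))),
  per_gene_depth = 350, n_replicates = 3, seed = 2)

pairing <- data.frame(treat = paste0("treat_rep", 1:3),
                      ctrl  = paste0("ctrl_rep", 1:3))
res <- run_diricore(aln, tx, pairing)
head(res$tests[order(-res$tests$z), ], 3)
#>     codon        signal          z            p         p_bh flagged_increase
#> 1:    AAA  0.8608382878 6.63776671 1.592357e-11 9.713376e-10             TRUE
#> 2:    AAT -0.0005317215 0.15262743 4.393460e-01 7.337759e-01            FALSE
#> 3:    CTT -0.0016676027 0.14407553 4.427204e-01 7.337759e-01            FALSE
```

AAA is recovered as the only flagged codon: its mean signal of 0.86 log2
units (occupancy nearly doubled, diluted by each gene's own AAA content in
the expectation) sits 6.6 background standard deviations above the
out-of-frame null, while every unperturbed codon stays within noise of
zero. Correlating codon usage with the simulated nascent proteome:

```r
dev <- usage_deviation(codon_frequencies(tx))$set_deviation[, "AAA"]
pro <- simulate_proteome(tx, proteome_effect(beta = c(AAA = -0.05),
                                             sigma = 0.1,
                                             global_offset = -0.3),
                         n_replicates = 3, seed = 3)
dec <- decile_ranks(center_nsp(pro$table, pro$lysate_median))
decile_deviation_summary(dec, dev)
#>     decile  n median_dev        q25        q75            p
#>  1:      1 30  12.755475  11.280760 13.9344648 3.601304e-19
#>  2:      2 30   7.869806   5.602680  8.8063869 2.353351e-12
#>  3:      3 30  -0.665776  -1.328800 -0.2326144 2.123203e-04
#>  ...
#> 10:     10 30  -3.570945  -3.952331 -3.0588677 7.255639e-09
```

The most-decreased deciles (1–2) are dominated by the AAA-enriched group
(median AAA deviation ≈ +13 and +8 percentage points versus a global
median below zero), and the decile medians fall monotonically — the
usage–synthesis correlation the effect model injected. The whole-lysate
median (−0.30 here) absorbed the global offset before ranking.

A thin command-line interface over the same functions is installed at
`inst/cli/ribocodon` (subcommands `simulate`, `occupancy`, `shifttest`,
`codonusage`, `correlate`); see the vignette for the statistical details
and design choices.

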