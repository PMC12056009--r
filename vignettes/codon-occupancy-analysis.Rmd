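---
title: "Codon-level translational analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level translational analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocodon)
```

# Scope

`ribocodon` implements the codon-level statistical layer of a translational
control study: differential ribosome codon reading from ribosome-profiling
footprints, an empirical significance test built from out-of-frame shifts,
per-transcript codon usage deviation, and the correlation of that deviation
with nascent-proteome fold changes. The motivating biology is wobble-uridine
(U34) tRNA modification: the mcm5s2 modification of U34 enhances decoding of
the three VAA codons — AAA (Lys), CAA (Gln), GAA (Glu); the fourth NAA
triplet, TAA, is a stop codon and not translated. Loss of the modifying
enzymes slows elongation at VAA codons (visible as increased ribosome A-site
occupancy) and depresses the synthesis of proteins encoded by VAA-rich
mRNAs, most prominently ribosomal proteins, whose mRNAs are strongly
AAA-enriched.

Everything upstream of these statistics — read trimming, UMI handling, rRNA
removal, alignment, spectral quantification, moderated differential
expression — is out of scope; the package consumes footprint alignments in
transcript coordinates and per-gene log2 ratio tables.

# Occupancy model

## Site assignment

A ribosome-protected fragment of 27–34 nt places the ribosomal A-site at
nucleotide 12 and the P-site at nucleotide 15 downstream of its 5′ end.
Coordinates are 0-based and half-open throughout; the site nucleotide is the
*first* nucleotide of the site codon. For a read with 5′ end $p$ on a
transcript whose CDS starts at $s$, the site is $p + \delta$
($\delta = 12$ or $15$), the frame is $(p + \delta - s) \bmod 3$ and the
codon index $(p + \delta - s) \operatorname{div} 3$. Only frame-0 sites are
counted; reads shorter than 27 nt are discarded (`min_read_length`,
matching the fragment-size filter applied to real libraries).

## Gene-level normalization

Raw per-codon counts confound dwell with codon *composition*: a codon that
is simply frequent collects reads without being slow. The package therefore
normalizes within genes. With $n_{g,c}$ the frame-0 site counts of codon $c$
on gene $g$, $N_g = \sum_c n_{g,c}$, and $e_{g,c}$ gene $g$'s codon
frequency,

$$ O_c = \sum_g n_{g,c}, \qquad
   E_c = \sum_g N_g \, e_{g,c}, \qquad
   o_c = O_c / E_c . $$

Under codon-indifferent elongation $o_c = 1$ for every codon, whatever the
gene set's composition, and $\sum_c O_c = \sum_c E_c$ holds exactly
(a conservation identity the tests assert to $10^{-12}$). We use this single
pooled observed-over-expected estimator rather than averaging per-gene
ratios: the pooled form is exact at any composition and remains stable when
per-gene coverage is low, where per-gene ratios are noisy or undefined.
Genes with fewer than `min_reads_per_gene` (default 64) frame-0 reads are
excluded from the normalization entirely, and the exclusion list is
reported; the default is a coverage heuristic, not a published constant, and
is configurable.

## Differential signal

For conditions measured in matched replicates, the per-codon differential
signal in pair $r$ is $\log_2(o_c^{\text{treat},r} / o_c^{\text{ctrl},r})$
and the reported signal $s_c$ is the arithmetic mean over pairs — replicate
pairs are compared first and averaged second, mirroring how replicate means
are reported in this kind of experiment. Codons with zero or undefined
occupancy in any member of any pair are dropped from testing and listed.

## Subset reanalysis

`subset_analysis()` (and the `subset` argument of `run_diricore()`) re-runs
the identical computation on a stated transcript subset, e.g. an
AAA-enriched ribosomal-protein-like class. Empty or unmatched subsets are
hard errors naming the offending ids, because a silently shrunken universe
would change the normalization.

# The shift null

A per-codon signal needs a reference distribution, and biological codon
effects rule out using the in-frame signals themselves. The package builds
an empirical null by *shifting the read-out one nucleotide off the codon*:
for each shift $\pm 1$, the full pipeline is recomputed with the counted
trinucleotide starting at $p + \delta \pm 1$ — a triplet that straddles a
codon boundary — while the read set itself (frame-0 at the unshifted site)
is unchanged, and the per-gene expected frequencies are recomputed over the
gene's trinucleotides at that frame offset. Off-boundary triplets are not
decoded as units by the ribosome, so their differential "signals" carry the
technical and sampling variability of the dataset but no codon-level dwell
effect. The per-codon mean signals at both shifts, over the 61 sense-codon
trinucleotides, are pooled into one background $B$ per dataset (up to
$|B| = 122$ values); pooling across codons and shifts was chosen over
per-codon nulls for sample-size reasons — 61 codons cannot support 61
separate empirical distributions.

Two design points deserve emphasis:

* **The frame filter is applied at the unshifted site.** Re-imposing
  frame 0 *after* the shift would select a disjoint read population (empty
  in data with perfect periodicity); keeping the in-frame reads and moving
  only the read-out makes the background a genuine re-analysis of the same
  data one nucleotide out of register. With this definition the background
  is identically zero when treat and ctrl are the same data (a degenerate
  case the code rejects), and relabeling the shifts leaves it unchanged.
* **The null is approximately, not exactly, signal-free.** A strong dwell
  change at codon X also perturbs the off-boundary triplets overlapping X
  (e.g. the NAA/AAN neighbours of a slowed AAA). This inflates the
  background spread slightly under strong alternatives, making the Z-test
  conservative rather than anticonservative.

The in-frame signal is then standardized, $z_c = (s_c - \mu_B)/\sigma_B$
(sample s.d., denominator $n-1$; a plain Z-test, no small-sample $t$
correction at $n \approx 122$), with a one-sided upper-tail p-value by
default, since occupancy *increases* are the effects of interest;
`two_sided = TRUE` is available. Raw p-values are reported and flagged at
`alpha` with no multiplicity adjustment by default; a Benjamini–Hochberg
column accompanies them. The normality of $B$ is a *check*, not a gate:
Anderson–Darling and Shapiro–Wilk statistics and q–q points are always
computed, and a Shapiro–Wilk p below `sw_threshold` (default 0.01) marks
the results as having a non-normal background with a warning, but testing
proceeds.

# Codon usage deviation

Per-transcript codon frequencies $u_{t,c}$ are percentages of the
transcript's sense codons (terminal stop excluded; rows sum to 100). The
reference $r_c$ is the *unweighted* mean of $u_{t,c}$ over transcripts —
each gene counts once regardless of CDS length; length-weighted pooling was
rejected because the reference should describe the typical transcript, not
the typical codon position. The deviation is the subtraction
$d_{t,c} = u_{t,c} - r_c$ in percentage points, and codon-set deviations
are sums of member deviations. Two identities follow and are asserted to
$10^{-9}$: $\sum_c d_{t,c} = 0$ for every transcript, and the non-VAA set
deviation is exactly $-$(VAA deviation). Which transcript universe defines
the reference (all annotated, or only proteome-detected genes) is left to
the caller: `usage_deviation()` accepts an externally computed reference,
so both conventions are supported without baking in a choice.

# Proteome correlation

Pulsed-SILAC ratios of newly synthesized proteins mix per-gene regulation
with the global synthesis-rate difference between conditions. The
whole-lysate median log2 ratio estimates the global component and is
subtracted from every record (`center_nsp()`). Genes are then
replicate-averaged (unweighted mean — replicates are treated as exchangeable
measurements), sorted, and cut into equal-count deciles, decile 1 holding
the ~10% most decreased genes; ties are broken by stable input order and
bin sizes differ by at most 1. Per decile, the summary reports the median
and interquartile range of a chosen codon-set deviation and a two-sided
Wilcoxon rank-sum p-value (normal approximation with tie correction)
against all *other* quantified genes — the complement was chosen as the
comparator so the two groups are disjoint; the figure-style "median of all
quantified genes" reference line is reported alongside. Whether the
comparator should instead be the full distribution or adjacent deciles is a
convention choice; the complement is the default here and the set-level
summary (`set_level_summary()`) deliberately uses all quantified genes
instead, so the boundary case "set = everything" returns p ≈ 1 rather than
an empty comparison. No multiplicity adjustment is applied across deciles.

# The synthetic-data generator

No generative model for these data is published; the simulator is a
stand-in built so that every downstream assumption is explicit and every
parameter recoverable, and its parameters are calibration devices, not
empirical estimates.

* **Transcriptomes** (`generate_transcriptome()`): gene groups with
  relative codon sampling weights; CDS lengths uniform on 150–650 codons by
  default (the span of typical mammalian CDSs); per-gene codon propensities
  drawn from a Dirichlet around the group weights with concentration
  `usage_dispersion = 150`, giving a between-gene AAA-usage spread of
  ~1.2 percentage points (binomial plus Dirichlet), comparable to real
  transcriptomes — pure multinomial sampling (set
  `usage_dispersion = Inf`) is unrealistically tight for studying
  usage–phenotype correlations. UTRs default to 36 nt; the 5′ UTR must be
  ≥ 15 nt so every CDS codon is A-site-observable by a ≥ 27-nt read even
  under 1-nt frame noise, avoiding edge-codon bias in the expectation.
* **Footprints** (`simulate_footprints()`): the A-site codon is sampled
  within each gene proportionally to the condition's dwell weights;
  `frame_noise` (default 0.1) displaces the recorded 5′ end by ±1 nt for
  that fraction of reads; read lengths are uniform on 27–33 nt, honoring
  the ≥ 27 nt filter. Depth is exactly `per_gene_depth` reads per gene per
  sample, so conservation is checkable. Ground-truth dwell tables ride
  along as an attribute (and as sidecar TSVs from the CLI).
* **Proteome** (`simulate_proteome()`): per-gene
  $\log_2\text{FC} = \text{offset} + \sum_s \beta_s d_{t,s} +
  \mathcal N(0, \sigma)$, with the lysate normalizer simulated as the
  median of per-gene lysate ratios around the same offset.

What the simulator does *not* emulate: sequence-level read errors,
alignment ambiguity, UMI duplication, position-dependent coverage decay
along the CDS, correlated replicates, or missing proteins in the proteome.
Passing tests on these data show that the statistics recover what they are
defined to recover under their own assumptions — not that those assumptions
hold in any particular real library.

# Numerical choices and degenerate inputs

* Deviations and occupancies are plain double arithmetic; identities are
  asserted at 1e-9 (deviations) and 1e-12 (conservation) rather than exact
  equality.
* A background with fewer than 30 defined values refuses to test; a
  constant background (e.g. treat ≡ ctrl) is a hard "degenerate
  background" error.
* Codons with zero expected count are undefined, omitted from profiles and
  reported; a zero occupancy in any replicate drops the codon from signal
  testing.
* Decile ties: stable input order (radix sort), so results are reproducible
  across runs for identical input tables.
* All generators take a single integer seed and are byte-reproducible given
  it.

# Problem sizes used in the packaged checks

The packaged calibration and recovery checks run at 200 genes ×
250–500 reads/gene/sample (5×10⁴–10⁵ reads per sample) with 3 replicate
pairs over 20–50 simulation seeds, and the decile analyses at 2000 genes —
sizes at which the expected behaviours (flag rate ≈ α, AAA recovery,
monotone decile trend) are comfortably resolved on a single CPU in a few
minutes.

# Worked example

```{r example, eval = FALSE}
tx <- generate_transcriptome(list(
  gene_group("bulk", 240),
  gene_group("RP-like", 60, codon_weights = c(AAA = 10))), seed = 1)

aln <- simulate_footprints(
  tx, list(ctrl = dwell_model(), treat = dwell_model(dwell = c(AAA = 2))),
  per_gene_depth = 350, n_replicates = 3, seed = 2)

pairing <- data.frame(treat = paste0("treat_rep", 1:3),
                      ctrl  = paste0("ctrl_rep", 1:3))
res <- run_diricore(aln, tx, pairing)
head(res$tests[order(-res$tests$z), ])

dev <- usage_deviation(codon_frequencies(tx))$set_deviation[, "AAA"]
pro <- simulate_proteome(tx, proteome_effect(beta = c(AAA = -0.05),
                                             sigma = 0.1,
                                             global_offset = -0.3),
                         n_replicates = 3, seed = 3)
dec <- decile_ranks(center_nsp(pro$table, pro$lysate_median))
decile_deviation_summary(dec, dev)
```

# Known limitations

* The out-of-frame background is a single pooled distribution per dataset;
  codon-specific nulls and permutation/bootstrap alternatives are not
  implemented.
* The normalization assumes uniquely assigned reads and one canonical CDS
  per gene; multi-mapping resolution and canonical-transcript selection are
  upstream concerns.
* P-site analysis (offset 15) is supported by the same machinery but has no
  dedicated diagnostics.
* The Wilcoxon comparisons are marginal per decile/set; no joint trend test
  is provided beyond the Spearman correlation of decile medians used in the
  checks.
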