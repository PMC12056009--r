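# Six-codon worked example: 12-nt 5' UTR, CDS AAA GAA AAA CCC GGG TTT TAA,
# 12-nt 3' UTR. Sense codons: AAA GAA AAA CCC GGG TTT.
worked_example_tx <- function() {
  transcript_set(
    gene_id = "g1",
    sequence = paste0("GCGCGCGCGCGC", "AAAGAAAAACCCGGGTTTTAA", "GCGCGCGCGCGC"),
    cds_start = 12L, cds_end = 33L
  )
}

# reads whose A-sites (offset 12) hit codons 0..5 with multiplicities
# 5,1,1,1,1,1 -> codon counts AAA=6, GAA=1, CCC=1, GGG=1, TTT=1
worked_example_aln <- function(sample = "treat_rep1") {
  idx <- c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5)
  data.frame(
    sample = sample,
    transcript_id = "g1",
    five_prime_pos = 12L + 3L * idx - 12L,
    read_length = 27L
  )
}

# control reads placed proportionally to codon composition (2 per codon
# position) -> observed equals expected, occupancy 1 for every codon
uniform_control_aln <- function(sample = "ctrl_rep1") {
  idx <- rep(0:5, each = 2)
  data.frame(
    sample = sample,
    transcript_id = "g1",
    five_prime_pos = 12L + 3L * idx - 12L,
    read_length = 27L
  )
}

# small two-condition simulated dataset shared by several tests
small_simulation <- function(n_genes = 60, depth = 400, n_rep = 2, seed = 42,
                             treat_dwell = NULL, frame_noise = 0.1) {
  tx <- generate_transcriptome(gene_group("bulk", n_genes,
                                          n_codons = c(120L, 400L)),
                               seed = seed)
  conds <- list(ctrl = dwell_model(frame_noise = frame_noise),
                treat = dwell_model(dwell = treat_dwell,
                                    frame_noise = frame_noise))
  aln <- simulate_footprints(tx, conds, per_gene_depth = depth,
                             n_replicates = n_rep, seed = seed + 1)
  pairing <- data.frame(treat = paste0("treat_rep", seq_len(n_rep)),
                        ctrl = paste0("ctrl_rep", seq_len(n_rep)))
  list(tx = tx, aln = aln, pairing = pairing)
}
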