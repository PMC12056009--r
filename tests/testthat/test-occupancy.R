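test_that("site assignment maps 5' positions to frames and codon indices", {
  # A-site of a read starting at 0 with a CDS at 12 is codon 0, frame 0
  a <- assign_site(0, cds_start = 12, cds_end = 33, offset = 12)
  expect_equal(a$codon_index, 0L)
  expect_equal(a$frame, 0L)
  # one nt downstream: out of frame
  expect_equal(assign_site(1, 12, 33, 12)$frame, 1L)
  # P-site offset 15 on the same read: next codon, frame 0
  p <- assign_site(0, 12, 33, offset = 15)
  expect_equal(p$codon_index, 1L)
  expect_equal(p$frame, 0L)
  # site before the CDS
  expect_false(assign_site(0, 30, 60, 12)$in_cds)
  expect_error(assign_site(0, 12, 33, offset = 9), "offset")
})

test_that("codon counting reproduces the worked example by hand", {
  tx <- worked_example_tx()
  aln <- worked_example_aln()
  cnt <- codon_counts(aln, tx, min_reads_per_gene = 1)
  got <- setNames(cnt$counts$count, cnt$counts$codon)
  expect_equal(got[c("AAA", "GAA", "CCC", "GGG", "TTT")],
               c(AAA = 6L, GAA = 1L, CCC = 1L, GGG = 1L, TTT = 1L))
  expect_equal(cnt$gene_totals$n_reads, 10L)
})

test_that("read and gene filters are enforced", {
  tx <- worked_example_tx()
  aln <- worked_example_aln()
  # a 26-nt read is discarded (< 27 nt filter)
  aln$read_length[1] <- 26L
  cnt <- codon_counts(aln, tx, min_reads_per_gene = 1)
  expect_equal(sum(cnt$counts$count), 9L)
  # all reads out of frame: gene contributes nothing and is excluded
  aln2 <- worked_example_aln()
  aln2$five_prime_pos <- aln2$five_prime_pos + 1L
  cnt2 <- codon_counts(aln2, tx, min_reads_per_gene = 1)
  expect_equal(nrow(cnt2$counts), 0L)
  expect_error(normalized_occupancy(cnt2, tx), "no genes pass")
  # below min_reads_per_gene: excluded and reported
  cnt3 <- codon_counts(worked_example_aln(), tx, min_reads_per_gene = 64)
  expect_equal(nrow(cnt3$counts), 0L)
  expect_equal(cnt3$excluded$gene_id, "g1")
  # unknown transcripts are dropped with a warning
  aln4 <- rbind(worked_example_aln(),
                data.frame(sample = "treat_rep1", transcript_id = "ghost",
                           five_prime_pos = 0L, read_length = 27L))
  expect_warning(cnt4 <- codon_counts(aln4, tx, min_reads_per_gene = 1),
                 "ghost")
  expect_equal(sum(cnt4$counts$count), 10L)
})

test_that("normalized occupancy matches the hand-computed worked example", {
  tx <- worked_example_tx()
  cnt <- codon_counts(worked_example_aln(), tx, min_reads_per_gene = 1)
  prof <- normalized_occupancy(cnt, tx)
  # e_AAA = 2/6, N = 10 -> E_AAA = 10/3, O_AAA = 6, o_AAA = 1.8
  aaa <- prof[prof$codon == "AAA", ]
  expect_equal(aaa$expected, 10 / 3)
  expect_equal(aaa$observed, 6)
  expect_equal(aaa$occupancy, 1.8)
  # conservation: sum O = sum E = reads used
  expect_equal(sum(prof$observed), sum(prof$expected), tolerance = 1e-12)
  expect_equal(sum(prof$observed), 10)
  # uniform placement: occupancy 1 everywhere
  prof_u <- normalized_occupancy(
    codon_counts(uniform_control_aln(), tx, min_reads_per_gene = 1), tx)
  expect_true(all(abs(prof_u$occupancy - 1) < 1e-12))
})

test_that("pooled normalization is invariant to splitting reads across genes", {
  # two genes with identical composition, one with 10x the reads, give the
  # same occupancy as the pooled single-gene computation
  seq1 <- worked_example_tx()$sequence
  tx2 <- transcript_set(c("g1", "g2"), c(seq1, seq1), c(12L, 12L),
                        c(33L, 33L))
  a1 <- worked_example_aln()
  a10 <- do.call(rbind, replicate(10, worked_example_aln(), simplify = FALSE))
  a10$transcript_id <- "g2"
  prof2 <- normalized_occupancy(
    codon_counts(rbind(a1, a10), tx2, min_reads_per_gene = 1), tx2)
  prof1 <- normalized_occupancy(
    codon_counts(worked_example_aln(), worked_example_tx(),
                 min_reads_per_gene = 1), worked_example_tx())
  m <- merge(as.data.frame(prof1), as.data.frame(prof2), by = "codon")
  expect_equal(m$occupancy.x, m$occupancy.y, tolerance = 1e-12)
})

test_that("expected counts depend on composition, not codon order", {
  tx <- generate_transcriptome(gene_group("bulk", 4, n_codons = 60L),
                               seed = 8)
  set.seed(1)
  perm <- tx
  for (i in seq_len(nrow(tx))) {
    cod <- cds_codons(tx, include_stop = TRUE)[[i]]
    n <- length(cod)
    shuffled <- c(sample(cod[-n]), cod[n])
    perm$sequence[i] <- paste0(substr(tx$sequence[i], 1, tx$cds_start[i]),
                               paste(shuffled, collapse = ""),
                               substr(tx$sequence[i], tx$cds_end[i] + 1,
                                      nchar(tx$sequence[i])))
  }
  aln <- simulate_footprints(tx, list(c1 = dwell_model(frame_noise = 0)),
                             per_gene_depth = 200, seed = 3)
  e1 <- normalized_occupancy(codon_counts(aln, tx, min_reads_per_gene = 1), tx)
  e2 <- normalized_occupancy(codon_counts(aln, perm, min_reads_per_gene = 1),
                             perm)
  m <- merge(e1[, c("codon", "expected")], e2[, c("codon", "expected")],
             by = "codon")
  expect_equal(m$expected.x, m$expected.y, tolerance = 1e-12)
})

test_that("occupancy matches brute-force enumeration on small inputs", {
  # random tiny datasets: <= 3 genes, <= 50 reads, exact agreement
  for (seed in 1:4) {
    tx <- generate_transcriptome(gene_group("t", 3, n_codons = c(20L, 40L)),
                                 seed = seed)
    aln <- simulate_footprints(tx, list(s1 = dwell_model(frame_noise = 0.2)),
                               per_gene_depth = 16, seed = seed + 10)
    for (shift in c(-1L, 0L, 1L)) {
      cnt <- ribocodon:::site_counts(aln, tx, shift = shift,
                                     min_reads_per_gene = 1L)
      got <- as.data.frame(normalized_occupancy(cnt, tx))
      ref <- oracle_occupancy(aln, tx, shift = shift, min_reads_per_gene = 1L)
      expect_equal(got$codon, ref$codon)
      expect_equal(got$observed, ref$observed)
      expect_equal(got$expected, ref$expected, tolerance = 1e-12)
      expect_equal(got$occupancy, ref$occupancy, tolerance = 1e-12)
    }
  }
})

test_that("frame fractions behave under zero frame noise", {
  # with frame_noise = 0 every read is frame 0 at offset 12 and never at 11/13
  sim <- small_simulation(n_genes = 10, depth = 200, n_rep = 1, seed = 4,
                          frame_noise = 0)
  aln <- merge(sim$aln, sim$tx[, c("gene_id", "cds_start")],
               by.x = "transcript_id", by.y = "gene_id")
  frame_at <- function(off) (aln$five_prime_pos + off - aln$cds_start) %% 3
  expect_true(all(frame_at(12) == 0))
  expect_true(all(frame_at(11) != 0))
  expect_true(all(frame_at(13) != 0))
})

test_that("differential signal averages matched replicate pairs", {
  tx <- worked_example_tx()
  aln <- rbind(worked_example_aln("treat_rep1"),
               uniform_control_aln("ctrl_rep1"))
  prof <- normalized_occupancy(codon_counts(aln, tx, min_reads_per_gene = 1),
                               tx)
  sig <- differential_signal(prof,
                             data.frame(treat = "treat_rep1",
                                        ctrl = "ctrl_rep1"))
  expect_equal(sig[sig$codon == "AAA", ]$mean_signal, log2(1.8),
               tolerance = 1e-12)
  # identical treat and ctrl -> all signals zero
  aln2 <- rbind(worked_example_aln("a"), worked_example_aln("b"))
  prof2 <- normalized_occupancy(codon_counts(aln2, tx, min_reads_per_gene = 1),
                                tx)
  sig2 <- differential_signal(prof2, data.frame(treat = "a", ctrl = "b"))
  expect_true(all(sig2$mean_signal == 0))
  # mean across two replicate pairs
  aln3 <- rbind(worked_example_aln("t1"), uniform_control_aln("c1"),
                worked_example_aln("t2"), uniform_control_aln("c2"))
  prof3 <- normalized_occupancy(codon_counts(aln3, tx, min_reads_per_gene = 1),
                                tx)
  sig3 <- differential_signal(prof3, data.frame(treat = c("t1", "t2"),
                                                ctrl = c("c1", "c2")))
  expect_equal(sig3[sig3$codon == "AAA", ]$mean_signal,
               mean(c(log2(1.8), log2(1.8))))
  expect_error(differential_signal(prof3, data.frame(treat = "t1",
                                                     ctrl = "missing")),
               "lacks samples")
})

test_that("subset analysis restricts and validates the gene universe", {
  sim <- small_simulation(n_genes = 12, depth = 300, n_rep = 1, seed = 6)
  full <- normalized_occupancy(
    codon_counts(sim$aln, sim$tx, min_reads_per_gene = 1), sim$tx)
  all_ids <- sim$tx$gene_id
  sub_all <- subset_analysis(sim$aln, sim$tx, all_ids, min_reads_per_gene = 1)
  m <- merge(as.data.frame(full), as.data.frame(sub_all$profile),
             by = c("sample", "codon"))
  expect_equal(m$occupancy.x, m$occupancy.y, tolerance = 1e-12)
  expect_error(subset_analysis(sim$aln, sim$tx, "not_a_gene"),
               "not_a_gene")
  # single gene of the worked example
  tx <- worked_example_tx()
  s1 <- subset_analysis(worked_example_aln(), tx, "g1",
                        min_reads_per_gene = 1)
  expect_equal(s1$profile[s1$profile$codon == "AAA", ]$occupancy, 1.8)
})
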