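test_that("FPKM follows the closed form and rejects zero lengths", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_error(compute_fpkm(10, 0, 1e6), "positive")
  set.seed(53)
  counts <- rpois(50, 200); lengths <- sample(500:5000, 50); tot <- 2e7
  expect_equal(compute_fpkm(counts, lengths, tot),
               sapply(seq_len(50), function(i)
                 (counts[i] / (lengths[i] / 1e3)) / (tot / 1e6)))
})

test_that("pausing index is count/FPKM, missing at zero FPKM, scale-equivariant", {
  expect_equal(pausing_index(500, 10), 50)
  expect_true(is.na(pausing_index(500, 0)))
  counts <- c(100, 250, 40); fpkm <- c(5, 10, 2)
  pi1 <- pausing_index(counts, fpkm)
  expect_equal(pausing_index(2 * counts, fpkm), 2 * pi1)
  expect_equal(pausing_index(counts, 2 * fpkm), pi1 / 2)
})

test_that("planted pausing indices are recovered through the full quantification", {
  sim <- small_sim(seed = 46L, n_genes = 150L, n_elements = 0L)
  cov5 <- lapply(sim$reads, build_end_coverage, end_kind = "five_prime")
  re <- suppressMessages(reannotate_tss(sim_annotation(sim), cov5))
  tss <- final_tss_table(re)
  pt <- suppressMessages(pausing_table(tss, cov5[[re$primary]], sim$fpkm))
  m <- merge(pt, sim$genes[, .(gene_id, planted_pi)], by = "gene_id")
  expect_gt(spearman_rho(m$planted_pi, m$pausing_index), 0.9)

  # exact inversion: pure TSS, no noise anywhere, single replicate
  sim0 <- small_sim(seed = 47L, n_genes = 40L, n_elements = 0L,
                    tss_purity = 1, noise_rate = 0, n_replicates = 1L,
                    divergent = list(fraction = 0, offset_range = c(80L, 200L),
                                     ratio = 0),
                    convergent = list(fraction = 0, offset_range = c(200L, 250L),
                                      ratio = 0),
                    pi_model = list(meanlog = log(50), sdlog = 0.8,
                                    fpkm_noise_sd = 0))
  cov0 <- lapply(sim0$reads, build_end_coverage, end_kind = "five_prime")
  re0 <- suppressMessages(reannotate_tss(sim_annotation(sim0), cov0))
  pt0 <- suppressMessages(pausing_table(final_tss_table(re0), cov0$rep1,
                                        sim0$fpkm))
  m0 <- merge(pt0, sim0$genes[, .(gene_id, planted_pi)], by = "gene_id")
  expect_equal(m0$pausing_index, m0$planted_pi)
})

test_that("3' metaprofile peaks at length - 1 for fixed-length TSS reads", {
  tss <- data.table(gene_id = "g1", occurrence = 1L, chrom = "chr1",
                    strand = "+", pos = 1000L, label = "g1")
  reads <- data.table(chrom = "chr1", start = 1000L, end = 1035L,
                      strand = "+", name = paste0("r", 1:20))
  cov3 <- build_end_coverage(reads, "three_prime")
  prof <- three_prime_metaprofile(cov3, tss)
  expect_equal(prof$peak_offset, 34L)
  expect_equal(sum(prof$profile), 20)  # conservation

  # uniform random 3' ends: no column dominates
  set.seed(59)
  upos <- sample(850:1150, 3000L, replace = TRUE)
  ureads <- data.table(chrom = "chr1", start = upos, end = upos + 35L,
                       strand = "+", name = "u")
  ucov <- build_end_coverage(ureads, "three_prime")
  uprof <- three_prime_metaprofile(ucov, tss)
  inner <- uprof$profile[abs(uprof$offsets) <= 140]
  expect_lt(max(inner), 2 * stats::median(inner))
})

test_that("reads assign to the nearest TSS with upstream tie-break", {
  tss <- data.table(gene_id = c("gA", "gB"), occurrence = 1L, chrom = "chr1",
                    strand = "+", pos = c(1000L, 1200L),
                    label = c("gA", "gB"))
  reads <- data.table(chrom = "chr1",
                      start = c(1050L, 1150L, 1100L, 900L),
                      end = c(1085L, 1185L, 1135L, 935L),
                      strand = "+", name = paste0("r", 1:4))
  asg <- assign_reads_to_genes(reads, tss)
  expect_equal(asg[order(offset5)]$gene_id, c("gA", "gB", "gA", "gA"))
  # r3 at 1100 is equidistant: upstream gene gA wins
  expect_equal(asg[offset5 == 100L, gene_id], "gA")
  # reads on the wrong strand are never assigned
  reads_m <- copy(reads)[, strand := "-"]
  expect_equal(nrow(assign_reads_to_genes(reads_m, tss)), 0L)
})

test_that("length-by-initiation drops over-length reads and reports mean/SEM", {
  asg <- data.table(gene_id = "g", occurrence = 1L,
                    offset5 = c(-7L, -7L, 3L, 3L, 3L),
                    offset3 = 0L, len = c(36L, 38L, 35L, 35L, 48L))
  out <- suppressMessages(length_by_initiation(asg))
  expect_equal(out[offset5 == -7L, mean_length], 37)
  expect_equal(out[offset5 == -7L, sem_length], 1)
  expect_equal(out[offset5 == 3L, n_reads], 2L)  # the 48-mer is dropped
  expect_equal(out[offset5 == 3L, mean_length], 35)
})

test_that("mean RNA length is flat in initiation position without a planted bonus", {
  sim <- small_sim(seed = 48L, n_genes = 400L, n_elements = 0L)
  cov5 <- lapply(sim$reads, build_end_coverage, end_kind = "five_prime")
  re <- suppressMessages(reannotate_tss(sim_annotation(sim), cov5))
  asg <- assign_reads_to_genes(sim$reads[[re$primary]], final_tss_table(re))
  lbp <- suppressMessages(length_by_initiation(asg))
  well <- lbp[n_reads >= 50]
  fit <- stats::lm(mean_length ~ offset5, data = well, weights = well$n_reads)
  expect_lt(abs(stats::coef(fit)["offset5"]), 0.1)
})

test_that("initiation classes flag underpowered bands and skip the statistic", {
  asg <- data.table(gene_id = "g", occurrence = 1L,
                    offset5 = rep(10L, 200L), offset3 = rep(44L, 200L),
                    len = 35L)
  cls <- initiation_class_profiles(asg)
  expect_true(cls$classes$upstream$underpowered)
  expect_false(cls$classes$downstream$underpowered)
  expect_true(is.na(cls$shift_statistic))
})
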