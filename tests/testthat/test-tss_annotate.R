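make_cov <- function(pos, count, strand = "+", chrom = "chr1") {
  counts <- data.table(chrom = chrom, strand = strand, pos = as.integer(pos),
                       count = as.integer(count))
  counts <- counts[, .(count = sum(count)), by = .(chrom, strand, pos)]
  setkey(counts, chrom, strand, pos)
  startseq:::new_end_coverage(counts, "five_prime", sum(counts$count))
}

test_that("peak call breaks ties by smallest offset magnitude, then upstream", {
  gene <- data.table(chrom = "chr1", strand = "+", tss = 1000L)
  cov <- make_cov(c(998L, 1007L), c(5L, 5L))
  expect_equal(call_peak_position(cov, gene)$peak_tss, 998L)
  cov2 <- make_cov(c(997L, 1003L), c(5L, 5L))
  expect_equal(call_peak_position(cov2, gene)$peak_tss, 997L)
  # same on the minus strand: upstream = larger coordinate
  gene_m <- data.table(chrom = "chr1", strand = "-", tss = 1000L)
  cov3 <- make_cov(c(997L, 1003L), c(5L, 5L), strand = "-")
  expect_equal(call_peak_position(cov3, gene_m)$peak_tss, 1003L)
})

test_that("peak call equals an exhaustive scan over every window offset", {
  set.seed(29)
  rcov <- random_coverage(2000L, pos_max = 12000L)
  genes <- data.table(chrom = "chrT",
                      strand = sample(c("+", "-"), 40L, replace = TRUE),
                      tss = sample(600:11000, 40L))
  calls <- startseq:::call_peaks_batch(
    rcov, genes[, .(chrom, strand, pos = tss)], window = 500L)
  for (i in seq_len(nrow(genes))) {
    orc <- oracle_peak_scan(rcov, "chrT", genes$strand[i], genes$tss[i], 500L)
    expect_equal(calls$window_count_[i], orc$window_total)
    if (!is.null(orc$best)) {
      expect_equal(calls$peak_offset[i], orc$best$offset)
      expect_equal(calls$peak_count[i], orc$best$count)
    } else {
      expect_true(is.na(calls$peak_offset[i]))
    }
  }
})

test_that("noise filter fails a gene below threshold in any replicate", {
  m <- rbind(c(9L, 50L), c(10L, 10L), c(100L, 9L))
  expect_equal(noise_filter(m), c(FALSE, TRUE, FALSE))
  expect_equal(noise_filter(matrix(10L, 1, 1)), TRUE)
})

test_that("offset fit is the plain sample mean/SD and flags degenerate input", {
  fit <- fit_offset_distribution(c(-1, 0, 1))
  expect_equal(fit$mean, 0)
  expect_equal(fit$sd, 1)
  expect_error(fit_offset_distribution(c(0, 0, 0)), "degenerate")
  expect_error(fit_offset_distribution(5), "at least 2")

  set.seed(31)
  draws <- rnorm(1000L, 5, 40)
  fit2 <- fit_offset_distribution(draws)
  expect_lt(abs(fit2$mean - 5), 3 * 40 / sqrt(1000))
  expect_lt(abs(fit2$sd - 40), 3 * 40 / sqrt(2 * 999))
})

test_that("distance filter is boundary-inclusive", {
  fit <- list(mean = 2, sd = 10)
  expect_true(distance_filter(12, fit))
  expect_false(distance_filter(13, fit))
  expect_true(distance_filter(-8, fit))
  expect_false(distance_filter(NA_real_, fit))
})

test_that("reannotation moves a clean off-annotation peak and applies filters", {
  # 10 genes whose pure peaks sit at varied offsets; the +8 gene must pass
  offs <- c(8L, -8L, 12L, -12L, 0L, 1L, 6L, -6L, 10L, -10L)
  genes <- data.table(gene_id = sprintf("g%02d", 1:10), occurrence = 1L,
                      chrom = "chr1", strand = "+",
                      tss = seq(5000L, by = 4000L, length.out = 10L))
  genes[, `:=`(body_start = tss, body_end = tss + 1000L)]
  pos <- genes$tss + offs
  cov1 <- make_cov(pos, rep(100L, 10L))
  cov2 <- make_cov(pos, rep(80L, 10L))
  re <- suppressMessages(
    reannotate_tss(genes, list(rep1 = cov1, rep2 = cov2)))
  expect_equal(re$primary, "rep1")
  g1 <- re$table[gene_id == "g01"]
  expect_equal(g1$status, "pass")
  expect_equal(g1$final_tss, genes$tss[1] + 8L)
  expect_equal(g1$shift_nt, 8L)
  expect_equal(g1$shift_class, "within_10")
  expect_equal(re$table[gene_id == "g05", shift_class], "identical")
  expect_equal(re$table[gene_id == "g06", shift_class], "within_5")

  cc <- shift_class_counts(re)
  expect_equal(unname(cc["gt_5"]),
               sum(abs(offs) > 5 & re$table$status == "pass"))

  # 9 reads in one replicate fails the gene regardless of the other
  cov2b <- make_cov(pos, c(9L, rep(80L, 9L)))
  re2 <- suppressMessages(
    reannotate_tss(genes, list(rep1 = cov1, rep2 = cov2b)))
  expect_equal(re2$table[gene_id == "g01", status], "fail_noise")
  # boundary: exactly 10 reads passes the noise filter
  cov2c <- make_cov(pos, c(10L, rep(80L, 9L)))
  re3 <- suppressMessages(
    reannotate_tss(genes, list(rep1 = cov1, rep2 = cov2c)))
  expect_true(re3$table[gene_id == "g01", status] != "fail_noise")
})

test_that("reads outside every gene window do not change any call", {
  set.seed(37)
  sim <- small_sim(seed = 43L, n_genes = 30L, n_elements = 0L,
                   noise_rate = 0)
  ann <- sim_annotation(sim)
  cov <- lapply(sim$reads, build_end_coverage, end_kind = "five_prime")
  re_a <- suppressMessages(reannotate_tss(ann, cov))
  far <- data.table(chrom = "chrS1", start = 300L, end = 335L, strand = "+",
                    name = "far")  # upstream of every gene window
  reads2 <- lapply(sim$reads, function(r) rbind(r, far))
  cov2 <- lapply(reads2, build_end_coverage, end_kind = "five_prime")
  re_b <- suppressMessages(reannotate_tss(ann, cov2))
  expect_equal(re_b$table, re_a$table)
})

test_that("offset signs follow gene orientation under mirroring", {
  sim <- small_sim(seed = 44L, n_genes = 40L, n_elements = 0L)
  ann <- sim_annotation(sim)
  L <- Biostrings::width(sim$genome)[1]
  cov <- lapply(sim$reads, build_end_coverage, end_kind = "five_prime")
  re_a <- suppressMessages(reannotate_tss(ann, cov))
  cov_m <- lapply(sim$reads, function(r)
    build_end_coverage(mirror_reads(r, L), "five_prime"))
  re_b <- suppressMessages(reannotate_tss(mirror_genes(ann, L), cov_m))
  a <- re_a$table[order(gene_id)]
  b <- re_b$table[order(gene_id)]
  expect_equal(b$peak_offset_rep1, a$peak_offset_rep1)
  expect_equal(b$status, a$status)
  expect_equal(b$shift_nt, a$shift_nt)
})
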