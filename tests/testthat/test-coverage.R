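test_that("read end positions follow the strand convention", {
  expect_equal(read_end_position(10L, 45L, "+", "five_prime"), 10L)
  expect_equal(read_end_position(10L, 45L, "-", "five_prime"), 44L)
  expect_equal(read_end_position(10L, 45L, "+", "three_prime"), 44L)
  expect_equal(read_end_position(10L, 45L, "-", "three_prime"), 10L)
})

test_that("end coverage equals a brute-force tally and conserves read count", {
  reads <- data.table(chrom = "chr1", start = 10L, end = 45L, strand = "+",
                      name = c("a", "b", "c"))
  cov <- build_end_coverage(reads, "five_prime")
  expect_equal(nrow(cov$counts), 1L)
  expect_equal(cov$counts$count, 3L)

  expect_equal(nrow(build_end_coverage(startseq:::empty_reads(),
                                       "five_prime")$counts), 0L)

  set.seed(5)
  rr <- random_reads(500L, chroms = c("chrT", "chrU"))
  for (ek in c("five_prime", "three_prime")) {
    cov <- build_end_coverage(rr, ek)
    expect_equal(sum(cov$counts$count), nrow(rr))
    tal <- oracle_end_tally(rr, ek)
    for (i in sample(nrow(cov$counts), 50L)) {
      row <- cov$counts[i]
      expect_equal(row$count, tal[[paste(row$chrom, row$strand, row$pos)]])
    }
    expect_equal(nrow(cov$counts), length(ls(tal)))
  }
})

test_that("window counts are boundary-inclusive and match the positional loop oracle", {
  counts <- data.table(chrom = "chr1", strand = "+",
                       pos = c(1000L, 1500L, 1501L, 499L, 500L),
                       count = c(1L, 2L, 4L, 8L, 16L))
  setkey(counts, chrom, strand, pos)
  cov <- startseq:::new_end_coverage(counts, "five_prime", 31L)
  # center only
  expect_equal(window_count(cov, "chr1", "+", 1000L, 0L, 0L), 1L)
  # +500 included, +501 excluded; -500 included, -501 excluded
  expect_equal(window_count(cov, "chr1", "+", 1000L, 500L, 500L),
               1L + 2L + 16L)
  expect_warning(expect_equal(
    window_count(cov, "chrX", "+", 1000L), 0L), "absent")

  set.seed(13)
  rcov <- random_coverage(600L, pos_max = 3000L)
  for (k in seq_len(250L)) {
    ch <- sample(c("chrT"), 1L)
    st <- sample(c("+", "-"), 1L)
    qs <- sample(c("same", "opposite"), 1L)
    center <- sample.int(3000L, 1L) - 1L
    up <- sample(0:60, 1L); down <- sample(0:60, 1L)
    expect_equal(
      window_count(cov = rcov, chrom = ch, strand = st, center = center,
                   up = up, down = down, query_strand = qs),
      oracle_window_count(rcov, ch, st, center, up, down, qs),
      info = sprintf("case %d", k))
  }
})

test_that("metagene matrices mirror minus-strand anchors and agree with window counts", {
  counts <- data.table(chrom = "chr1", strand = c("+", "-"),
                       pos = c(97L, 203L), count = c(1L, 1L))
  setkey(counts, chrom, strand, pos)
  cov <- startseq:::new_end_coverage(counts, "five_prime", 2L)
  mg_plus <- metagene_matrix(cov, data.table(chrom = "chr1", pos = 100L,
                                             strand = "+"), 5L, 5L)
  expect_equal(unname(mg_plus$matrix[1, "-3"]), 1L)
  mg_minus <- metagene_matrix(cov, data.table(chrom = "chr1", pos = 200L,
                                              strand = "-"), 5L, 5L)
  expect_equal(unname(mg_minus$matrix[1, "-3"]), 1L)

  set.seed(17)
  rcov <- random_coverage(500L, pos_max = 4000L)
  anchors <- data.table(chrom = "chrT",
                        pos = sample.int(3500L, 40L) + 200L,
                        strand = sample(c("+", "-"), 40L, replace = TRUE))
  mg <- metagene_matrix(rcov, anchors, 100L, 100L)
  wc <- startseq:::window_counts_batch(rcov, anchors, 100L, 100L)
  expect_equal(unname(rowSums(mg$matrix)), as.numeric(wc))
})

test_that("coverage and metagenes are invariant under genome mirroring", {
  set.seed(19)
  L <- 6000L
  reads <- random_reads(400L, pos_max = L - 100L)
  anchors <- data.table(chrom = "chrT", pos = sample(500:5000, 30L),
                        strand = sample(c("+", "-"), 30L, replace = TRUE))
  mg <- metagene_matrix(build_end_coverage(reads, "five_prime"),
                        anchors, 80L, 80L)
  m_reads <- mirror_reads(reads, L)
  m_anchors <- data.table(chrom = "chrT", pos = L - 1L - anchors$pos,
                          strand = fifelse(anchors$strand == "+", "-", "+"))
  mg_m <- metagene_matrix(build_end_coverage(m_reads, "five_prime"),
                          m_anchors, 80L, 80L)
  expect_equal(mg_m$matrix, mg$matrix)
})

test_that("spearman_rho matches rank-then-Pearson and handles degenerate input", {
  expect_equal(spearman_rho(1:3, 1:3), 1.0)
  expect_equal(spearman_rho(1:3, 3:1), -1.0)
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))

  set.seed(23)
  for (k in seq_len(50L)) {
    x <- sample(1:20, 50L, replace = TRUE)  # ties present
    y <- x + rnorm(50L, sd = 5)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  }
})
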