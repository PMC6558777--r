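peak_cov <- function(pos, count, strand, chrom = "chr1") {
  counts <- data.table(chrom = chrom, strand = strand, pos = as.integer(pos),
                       count = as.integer(count))
  setkey(counts, chrom, strand, pos)
  startseq:::new_end_coverage(counts, "five_prime", sum(counts$count))
}

test_that("greedy peak calling respects min count and summit separation", {
  cov <- peak_cov(1000L, 12L, "+")
  pk <- call_strand_peaks(cov)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 1000L)

  # second summit 100 nt away is suppressed at min_separation 150
  cov2 <- peak_cov(c(1000L, 1100L), c(12L, 11L), "+")
  pk2 <- call_strand_peaks(cov2)
  expect_equal(pk2$summit, 1000L)
  # but survives on the other strand
  cov3 <- peak_cov(c(1000L, 1100L), c(12L, 11L), c("+", "-"))
  expect_equal(nrow(call_strand_peaks(cov3)), 2L)

  expect_equal(nrow(call_strand_peaks(peak_cov(1000L, 9L, "+"))), 0L)
})

test_that("greedy peak calling equals a brute-force greedy over sorted positions", {
  set.seed(71)
  for (k in 1:20) {
    rcov <- random_coverage(150L, pos_max = 4000L, max_count = 25L)
    got <- call_strand_peaks(rcov, min_count = 10L, min_separation = 150L)
    # oracle: independent greedy, descending count then ascending position
    want <- rcov$counts[count >= 10L][order(-count, pos)]
    acc <- list()
    for (i in seq_len(nrow(want))) {
      row <- want[i]
      ok <- TRUE
      for (a in acc) {
        if (a$chrom == row$chrom && a$strand == row$strand &&
            abs(a$pos - row$pos) < 150L) { ok <- FALSE; break }
      }
      if (ok) acc[[length(acc) + 1L]] <- as.list(row)
    }
    want_dt <- if (length(acc)) rbindlist(acc) else
      data.table(chrom = character(), strand = character(), pos = integer())
    setorder(want_dt, chrom, pos, strand)
    expect_equal(got[, .(chrom, strand, summit)],
                 want_dt[, .(chrom, strand, summit = pos)])
  }
})

test_that("promoter exclusion is summit-based and inclusive at the boundary", {
  peaks <- data.table(peak_id = c("p1", "p2"), chrom = "chr1", strand = "+",
                      summit = c(13000L, 13001L), summit_count = 12L,
                      start = c(12990L, 12991L), end = c(13010L, 13011L))
  tss <- data.table(chrom = "chr1", pos = 10000L)
  kept <- suppressMessages(filter_promoter_proximal(peaks, tss))
  expect_equal(kept$peak_id, "p2")  # 3000 away removed, 3001 kept

  set.seed(73)
  rp <- data.table(peak_id = paste0("p", 1:200), chrom = "chrT", strand = "+",
                   summit = sample.int(50000L, 200L), summit_count = 10L)
  rp[, `:=`(start = summit - 5L, end = summit + 5L)]
  rtss <- data.table(chrom = "chrT", pos = sample.int(50000L, 30L))
  kept2 <- suppressMessages(filter_promoter_proximal(rp, rtss))
  keep_oracle <- sapply(seq_len(nrow(rp)), function(i)
    all(abs(rp$summit[i] - rtss$pos) > 3000L))
  expect_equal(kept2$peak_id, rp$peak_id[keep_oracle])
})

test_that("bidirectional merging needs >= 2 chained peaks with an opposite-strand adjacency", {
  peaks <- data.table(peak_id = c("a", "b"), chrom = "chr1",
                      strand = c("+", "-"), summit = c(1000L, 2500L),
                      summit_count = 12L, start = c(990L, 2490L),
                      end = c(1010L, 2510L))
  rg <- merge_bidirectional(peaks)
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$members, "a,b")
  expect_equal(c(rg$start, rg$end), c(990L, 2510L))

  same <- copy(peaks)[, strand := "+"]
  expect_equal(nrow(merge_bidirectional(same)), 0L)

  apart <- copy(peaks)[peak_id == "b", summit := 4001L]
  expect_equal(nrow(merge_bidirectional(apart)), 0L)
})

test_that("merging matches exhaustive chain enumeration on random small peak sets", {
  set.seed(79)
  for (k in seq_len(1000L)) {
    n <- sample(1:8, 1L)
    summit <- sort(sample.int(15000L, n))
    peaks <- data.table(peak_id = paste0("p", seq_len(n)),
                        chrom = sample(c("c1", "c2"), n, replace = TRUE),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        summit = summit, summit_count = 10L,
                        start = summit - 3L, end = summit + 3L)
    got <- merge_bidirectional(peaks, max_gap = 3000L)
    want <- oracle_merge(peaks, max_gap = 3000L)
    setorder(want, chrom, start)
    expect_equal(got[, .(chrom, start, end, n_peaks, members)],
                 want[, .(chrom, start, end, n_peaks, members)],
                 info = sprintf("case %d", k))
    # regions are non-overlapping and partition their member peaks
    if (nrow(got) > 1L) {
      by_chrom <- split(got, got$chrom)
      for (bc in by_chrom) {
        if (nrow(bc) > 1L) expect_true(all(bc$start[-1L] >= bc$end[-nrow(bc)]))
      }
    }
    members <- unlist(strsplit(got$members, ","))
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("novel transcript selection keeps multi-exon intergenic assemblies only", {
  known <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tref\tgene\t1000\t5000\t.\t+\t.\tgene_id "known1";'
  ), known)
  asm <- tempfile(fileext = ".gtf")
  writeLines(c(
    # 2-exon fully intergenic: retained
    'chr1\tstr\texon\t8000\t8200\t.\t+\t.\tgene_id "n1"; transcript_id "t1";',
    'chr1\tstr\texon\t8800\t9000\t.\t+\t.\tgene_id "n1"; transcript_id "t1";',
    # 1-exon intergenic: counted but not retained
    'chr1\tstr\texon\t12000\t12500\t.\t-\t.\tgene_id "n2"; transcript_id "t2";',
    # 2-exon but one exon shares 1 bp with the known gene body: not intergenic
    'chr1\tstr\texon\t5000\t5200\t.\t+\t.\tgene_id "n3"; transcript_id "t3";',
    'chr1\tstr\texon\t5900\t6000\t.\t+\t.\tgene_id "n3"; transcript_id "t3";'
  ), asm)
  out <- suppressMessages(select_novel_transcripts(asm, known))
  tx <- out$transcripts
  expect_equal(out$n_intergenic, 2L)
  expect_equal(out$n_multi_exon, 1L)
  expect_true(tx[transcript_id == "t1", retained])
  expect_true(tx[transcript_id == "t2", intergenic])
  expect_false(tx[transcript_id == "t2", retained])
  expect_false(tx[transcript_id == "t3", intergenic])
  expect_equal(out$multi_exon_fraction, 0.5)
})
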