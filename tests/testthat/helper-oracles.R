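# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation: plain loops over
# positions, all-pairs overlap checks, exhaustive scans.

library(data.table)

# sparse random coverage on one or more chromosomes
random_coverage <- function(n_pos, chroms = "chrT", pos_max = 5000L,
                            max_count = 30L, end_kind = "five_prime") {
  dt <- data.table(
    chrom = sample(chroms, n_pos, replace = TRUE),
    strand = sample(c("+", "-"), n_pos, replace = TRUE),
    pos = sample.int(pos_max, n_pos, replace = TRUE) - 1L
  )
  dt <- unique(dt)
  dt[, count := sample.int(max_count, .N, replace = TRUE)]
  setkey(dt, chrom, strand, pos)
  startseq:::new_end_coverage(dt, end_kind, sum(dt$count))
}

random_reads <- function(n, chroms = "chrT", pos_max = 5000L,
                         len_range = c(18L, 47L)) {
  start <- sample.int(pos_max, n, replace = TRUE) - 1L
  len <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
  data.table(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    name = paste0("r", seq_len(n))
  )
}

# positional-loop window count (anchor-oriented, inclusive boundaries)
oracle_window_count <- function(cov, ch, st, center, up, down,
                                query_strand = "same") {
  qs <- if (query_strand == "same") st else if (st == "+") "-" else "+"
  total <- 0L
  for (off in seq.int(-up, down)) {
    p <- if (st == "+") center + off else center - off
    row <- cov$counts[chrom == ch & strand == qs & pos == p]
    if (nrow(row)) total <- total + row$count
  }
  total
}

# all-pairs per-base overlap check
oracle_blacklist_keep <- function(reads, mask) {
  keep <- rep(TRUE, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(mask))) {
      if (reads$chrom[i] == mask$chrom[j] &&
          reads$start[i] < mask$end[j] && mask$start[j] < reads$end[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# exhaustive scan over every offset in the window; implementation tie rules
# (max count, then min |offset|, then upstream) applied explicitly
oracle_peak_scan <- function(cov, ch, st, tss, window) {
  best <- NULL
  total <- 0L
  for (off in seq.int(-window, window)) {
    p <- if (st == "+") tss + off else tss - off
    row <- cov$counts[chrom == ch & strand == st & pos == p]
    if (nrow(row) == 0L) next
    total <- total + row$count
    cand <- list(offset = off, count = row$count)
    if (is.null(best) ||
        cand$count > best$count ||
        (cand$count == best$count && abs(cand$offset) < abs(best$offset)) ||
        (cand$count == best$count && abs(cand$offset) == abs(best$offset) &&
         cand$offset < best$offset)) {
      best <- cand
    }
  }
  list(best = best, window_total = total)
}

# exhaustive merge oracle: every maximal run of consecutive-in-order peaks
# with gaps <= max_gap, kept iff >= 2 members and some adjacent pair differs
# in strand
oracle_merge <- function(peaks, max_gap) {
  peaks <- peaks[order(chrom, summit, strand)]
  out <- list()
  for (ch in unique(peaks$chrom)) {
    p <- peaks[chrom == ch]
    n <- nrow(p)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && p$summit[j + 1L] - p$summit[j] <= max_gap) j <- j + 1L
      if (j > i) {
        strands <- p$strand[i:j]
        if (any(strands[-1L] != strands[-length(strands)])) {
          out[[length(out) + 1L]] <- data.table(
            chrom = ch, start = min(p$start[i:j]), end = max(p$end[i:j]),
            n_peaks = j - i + 1L,
            members = paste(p$peak_id[i:j], collapse = ","))
        }
      }
      i <- j + 1L
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = integer(), end = integer(),
               n_peaks = integer(), members = character())
}

oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# reads table -> coverage via plain environment tally
oracle_end_tally <- function(reads, end_kind) {
  tal <- new.env()
  for (i in seq_len(nrow(reads))) {
    p <- if (end_kind == "five_prime") {
      if (reads$strand[i] == "+") reads$start[i] else reads$end[i] - 1L
    } else {
      if (reads$strand[i] == "+") reads$end[i] - 1L else reads$start[i]
    }
    key <- paste(reads$chrom[i], reads$strand[i], p)
    tal[[key]] <- (if (is.null(tal[[key]])) 0L else tal[[key]]) + 1L
  }
  tal
}

# mirror a read table / gene table through position -> L - 1 - position
mirror_reads <- function(reads, L) {
  data.table(chrom = reads$chrom,
             start = L - reads$end, end = L - reads$start,
             strand = fifelse(reads$strand == "+", "-", "+"),
             name = reads$name)
}

mirror_genes <- function(genes, L) {
  g <- copy(genes)
  g[, `:=`(tss = L - 1L - tss,
           strand = fifelse(strand == "+", "-", "+"),
           body_start = L - body_end, body_end = L - body_start)]
  setorder(g, chrom, tss)
  g[]
}

# small deterministic simulation shared by several test files
small_sim <- function(seed = 42L, n_genes = 80L, n_elements = 6L, ...) {
  simulate_startseq_experiment(
    simulate_config(seed = seed, n_genes = n_genes, n_elements = n_elements,
                    ...))
}
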