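# Strand-specific single-nucleotide 5'/3' end coverage and the window /
# metagene counting that every downstream stage is built on. Coverage is a
# sparse map (chrom, strand, pos) -> count so a toy chromosome and a full
# genome share one code path.

#' Genomic position of a read's 5' or 3' end
#'
#' Vectorized over reads. The 5' end of a plus-strand read is its interval
#' start; of a minus-strand read, its interval end - 1 (0-based half-open
#' convention). The 3' end is the opposite extremity.
#'
#' @param start,end Integer vectors, 0-based half-open read intervals.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param end_kind `"five_prime"` or `"three_prime"`.
#' @return Integer vector of genomic positions.
#' @export
read_end_position <- function(start, end, strand,
                              end_kind = c("five_prime", "three_prime")) {
  end_kind <- match.arg(end_kind)
  if (end_kind == "five_prime") {
    fifelse(strand == "+", start, end - 1L)
  } else {
    fifelse(strand == "+", end - 1L, start)
  }
}

new_end_coverage <- function(counts, end_kind, n_reads) {
  structure(list(counts = counts, end_kind = end_kind,
                 n_reads = as.integer(n_reads)),
            class = "end_coverage")
}

empty_counts <- function() {
  counts <- data.table(chrom = character(), strand = character(),
                       pos = integer(), count = integer())
  setkey(counts, chrom, strand, pos)
  counts
}

#' Build strand-specific single-nucleotide end coverage
#'
#' Tallies, per chromosome and strand, how many read 5' (or 3') ends fall on
#' each position. Total mass equals the number of input reads.
#'
#' @param reads Read table ([load_reads()]).
#' @param end_kind `"five_prime"` or `"three_prime"`.
#' @return An `end_coverage` object: `$counts` is a keyed `data.table`
#'   (`chrom`, `strand`, `pos`, `count`), `$end_kind` the end tallied,
#'   `$n_reads` the contributing read count.
#' @export
build_end_coverage <- function(reads, end_kind = c("five_prime", "three_prime")) {
  end_kind <- match.arg(end_kind)
  if (nrow(reads) == 0L) return(new_end_coverage(empty_counts(), end_kind, 0L))
  pos <- read_end_position(reads$start, reads$end, reads$strand, end_kind)
  counts <- data.table(chrom = reads$chrom, strand = reads$strand, pos = pos)[
    , .(count = .N), by = .(chrom, strand, pos)]
  setkey(counts, chrom, strand, pos)
  new_end_coverage(counts, end_kind, nrow(reads))
}

#' @export
print.end_coverage <- function(x, ...) {
  cat(sprintf("<end_coverage> %s ends of %d reads at %d positions\n",
              x$end_kind, x$n_reads, nrow(x$counts)))
  invisible(x)
}

# Batch window sums for a table of anchors. Offsets are anchor-oriented:
# positive offsets point downstream of the anchor (decreasing genomic
# coordinate on the minus strand). query_strand = "same" counts signal on the
# anchor's strand, "opposite" on the other strand (antisense analyses).
window_counts_batch <- function(cov, anchors, up, down,
                                query_strand = c("same", "opposite")) {
  query_strand <- match.arg(query_strand)
  a <- data.table(chrom = anchors$chrom, astrand = anchors$strand,
                  pos0 = anchors$pos, idx = seq_len(nrow(anchors)))
  a[, qstrand := if (query_strand == "same") astrand else
    fifelse(astrand == "+", "-", "+")]
  a[, lo := fifelse(astrand == "+", pos0 - up, pos0 - down)]
  a[, hi := fifelse(astrand == "+", pos0 + down, pos0 + up)]
  hits <- cov$counts[a,
    .(idx = i.idx, n = sum(x.count)),
    on = .(chrom, strand = qstrand, pos >= lo, pos <= hi),
    by = .EACHI, nomatch = NULL][, .(n = sum(n)), by = idx]
  out <- integer(nrow(anchors))
  out[hits$idx] <- as.integer(hits$n)
  out
}

# As above but returning every covered (anchor, offset, count) triple.
window_hits_batch <- function(cov, anchors, up, down,
                              query_strand = c("same", "opposite")) {
  query_strand <- match.arg(query_strand)
  a <- data.table(chrom = anchors$chrom, astrand = anchors$strand,
                  pos0 = anchors$pos, idx = seq_len(nrow(anchors)))
  a[, qstrand := if (query_strand == "same") astrand else
    fifelse(astrand == "+", "-", "+")]
  a[, lo := fifelse(astrand == "+", pos0 - up, pos0 - down)]
  a[, hi := fifelse(astrand == "+", pos0 + down, pos0 + up)]
  hits <- cov$counts[a,
    .(idx = i.idx, pos = x.pos, count = x.count,
      pos0 = i.pos0, astrand = i.astrand),
    on = .(chrom, strand = qstrand, pos >= lo, pos <= hi),
    nomatch = NULL]
  hits[, offset := fifelse(astrand == "+", pos - pos0, pos0 - pos)]
  hits[, .(idx, offset, count)]
}

#' Count read ends in a window around a position
#'
#' Sums coverage at anchor-oriented offsets `-up .. +down` from `center`,
#' both boundary offsets included (window width `up + down + 1`). On the
#' minus strand, positive offsets run toward decreasing genomic coordinates.
#'
#' @param cov An `end_coverage` object.
#' @param chrom Chromosome name.
#' @param strand Anchor strand, `"+"` or `"-"`; also the strand whose signal
#'   is counted unless `query_strand = "opposite"`.
#' @param center 0-based anchor position.
#' @param up,down Non-negative extents (nt) upstream/downstream of the anchor.
#' @param query_strand Count signal on the `"same"` strand as the anchor or
#'   the `"opposite"` one.
#' @return Integer count. Unknown chromosome yields 0 with a warning.
#' @export
window_count <- function(cov, chrom, strand, center, up = 500L, down = 500L,
                         query_strand = "same") {
  stopifnot(up >= 0L, down >= 0L)
  if (!chrom %in% unique(cov$counts$chrom)) {
    warning("chromosome ", chrom, " absent from coverage")
    return(0L)
  }
  window_counts_batch(
    cov, data.table(chrom = chrom, strand = strand, pos = center),
    up = up, down = down, query_strand = query_strand
  )
}

#' Anchor-oriented metagene count matrix
#'
#' Builds the anchors x offsets matrix of end counts around each anchor,
#' with minus-strand anchors mirrored so positive offsets always point
#' downstream of the anchor. Column sums of the matrix give the metagene
#' profile; row sums equal the corresponding [window_count()] values.
#'
#' @param cov An `end_coverage` object.
#' @param anchors `data.frame`/`data.table` with columns `chrom`, `pos`,
#'   `strand` and optionally `label` (defaults to row number).
#' @param flank_up,flank_down Window extents (offsets `-flank_up ..
#'   +flank_down`).
#' @param query_strand `"same"` or `"opposite"` (see [window_count()]).
#' @return A `metagene_matrix` object: `$matrix` (rows = anchors, columns =
#'   offsets), `$offsets`, `$anchors`.
#' @export
metagene_matrix <- function(cov, anchors, flank_up = 500L, flank_down = 500L,
                            query_strand = "same") {
  anchors <- as.data.table(anchors)
  if (is.null(anchors$label)) anchors[, label := as.character(seq_len(.N))]
  offsets <- seq.int(-flank_up, flank_down)
  m <- matrix(0L, nrow = nrow(anchors), ncol = length(offsets),
              dimnames = list(anchors$label, offsets))
  hits <- window_hits_batch(cov, anchors, up = flank_up, down = flank_down,
                            query_strand = query_strand)
  if (nrow(hits)) {
    m[cbind(hits$idx, hits$offset + flank_up + 1L)] <- hits$count
  }
  structure(list(matrix = m, offsets = offsets, anchors = anchors),
            class = "metagene_matrix")
}

#' Metagene profile (column sums of a metagene matrix)
#'
#' @param mg A [metagene_matrix()] object.
#' @return Named numeric vector of per-offset totals.
#' @export
metagene_profile <- function(mg) {
  colSums(mg$matrix)
}

#' Write a metagene matrix as TSV (rows = anchor labels, columns = offsets)
#'
#' @param mg A [metagene_matrix()] object.
#' @param path Output path.
#' @export
write_metagene_tsv <- function(mg, path) {
  out <- data.table(label = rownames(mg$matrix))
  out <- cbind(out, as.data.table(mg$matrix))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; `NA` when either vector has
#' zero rank variance or fewer than 3 complete pairs.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}
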