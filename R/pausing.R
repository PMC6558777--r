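# Promoter-proximal Pol II pausing quantification. The pausing index (PI) of
# a gene is its sense-strand short-capped-RNA count in the TSS +/- 500 bp
# window divided by the gene's expression level (FPKM): more 5'-capped short
# RNA per unit of mRNA output means more pausing. The 3' ends of the short
# RNAs mark the pause positions; anchoring reads on their own 5' ends
# separates distance-constrained from sequence-constrained pausing.

#' FPKM from raw counts
#'
#' `fpkm = count * 1e9 / (library_total * length)`.
#'
#' @param counts Per-gene read counts.
#' @param lengths Transcript lengths in nt (> 0).
#' @param library_total Total mapped reads in the library (> 0).
#' @return Numeric FPKM vector.
#' @export
compute_fpkm <- function(counts, lengths, library_total) {
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  stopifnot(library_total > 0)
  counts * 1e9 / (library_total * lengths)
}

#' Pausing index
#'
#' Ratio of the sense-strand TSS-window count to the gene's FPKM. Genes with
#' zero FPKM get `NA` (reported as missing, not infinite).
#'
#' @param tss_window_count Sense-strand 5'-end count in the TSS window.
#' @param fpkm Expression level of the same gene.
#' @return Numeric PI vector.
#' @export
pausing_index <- function(tss_window_count, fpkm) {
  fifelse(is.na(fpkm) | fpkm <= 0, NA_real_, tss_window_count / fpkm)
}

#' Per-gene pausing table
#'
#' Joins sense TSS-window counts (primary replicate) with an FPKM table and
#' computes the pausing index. Genes absent from the expression table, or
#' with zero FPKM, carry `NA` PI and are listed in the attached
#' `excluded` attribute.
#'
#' @param tss_table Final TSS anchors ([final_tss_table()]).
#' @param cov5 Primary-replicate 5'-end `end_coverage`.
#' @param fpkm_table `data.table` with `gene_id`, `fpkm`.
#' @param window Half-window in nt (default 500).
#' @return `data.table` with `gene_id`, `occurrence`, `tss_window_count`,
#'   `fpkm`, `pausing_index`.
#' @export
pausing_table <- function(tss_table, cov5, fpkm_table, window = 500L) {
  out <- data.table(
    gene_id = tss_table$gene_id, occurrence = tss_table$occurrence,
    tss_window_count = window_counts_batch(cov5, tss_table,
                                           up = window, down = window)
  )
  out <- merge(out, fpkm_table[, .(gene_id, fpkm)], by = "gene_id",
               all.x = TRUE, sort = FALSE)
  out[, pausing_index := pausing_index(tss_window_count, fpkm)]
  excluded <- out[is.na(pausing_index), gene_id]
  if (length(excluded))
    message(length(excluded), " genes excluded from PI (missing or zero FPKM)")
  setattr(out, "excluded", excluded)
  out[]
}

#' 3'-end metaprofile around final TSSs
#'
#' Column-sum profile of sense-strand RNA 3' ends over gene-oriented offsets
#' `-flank .. +flank` from each anchor, with the peak offset (pause summit).
#' An optional anchor grouping (e.g. top expression quartile) yields
#' per-group sub-profiles.
#'
#' @param cov3 3'-end `end_coverage`.
#' @param anchors Final TSS anchor table ([final_tss_table()]).
#' @param flank Half-window (default 150 nt).
#' @param groups Optional factor/character vector, one value per anchor.
#' @return List: `offsets`, `profile` (named totals), `peak_offset`,
#'   `group_profiles` (named list, when `groups` given).
#' @export
three_prime_metaprofile <- function(cov3, anchors, flank = 150L,
                                    groups = NULL) {
  mg <- metagene_matrix(cov3, anchors, flank_up = flank, flank_down = flank)
  prof <- metagene_profile(mg)
  peak <- profile_peak_offset(prof, mg$offsets)
  group_profiles <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(mg$matrix))
    group_profiles <- lapply(split(seq_along(groups), groups), function(i) {
      colSums(mg$matrix[i, , drop = FALSE])
    })
  }
  list(offsets = mg$offsets, profile = prof, peak_offset = peak,
       group_profiles = group_profiles)
}

profile_peak_offset <- function(profile, offsets) {
  if (all(profile == 0)) return(NA_integer_)
  cand <- which(profile == max(profile))
  cand <- cand[order(abs(offsets[cand]), offsets[cand])][1L]
  offsets[cand]
}

#' Assign reads to genes by sense-strand 5' end near the final TSS
#'
#' A read is assigned to a gene when it lies on the gene's strand and its 5'
#' end falls within +/- `flank` nt of the gene's final TSS, regardless of its
#' exact initiation position. Each read goes to at most one gene: the nearest
#' TSS wins, ties to the upstream gene (smaller coordinate on +, larger
#' on -).
#'
#' @param reads Read table.
#' @param tss_table Final TSS anchors ([final_tss_table()]).
#' @param flank Assignment half-window (default 150 nt).
#' @return `data.table` of assigned reads with `gene_id`, `occurrence`,
#'   `offset5`, `offset3` (gene-oriented offsets of the read's 5' and 3'
#'   ends from the final TSS) and `len`.
#' @export
assign_reads_to_genes <- function(reads, tss_table, flank = 150L) {
  r <- as.data.table(reads)
  r[, `:=`(pos5 = read_end_position(start, end, strand, "five_prime"),
           pos3 = read_end_position(start, end, strand, "three_prime"),
           ridx = .I)]
  t <- tss_table[, .(gene_id, occurrence, chrom, strand, tsspos = pos,
                     lo = pos - flank, hi = pos + flank)]
  hits <- t[r, on = .(chrom, strand, lo <= pos5, hi >= pos5), nomatch = NULL,
            .(ridx = i.ridx, gene_id = x.gene_id, occurrence = x.occurrence,
              tsspos = x.tsspos, pos5 = i.pos5, pos3 = i.pos3,
              strand = i.strand, len = i.end - i.start)]
  if (nrow(hits) == 0L) {
    return(data.table(gene_id = character(), occurrence = integer(),
                      offset5 = integer(), offset3 = integer(),
                      len = integer()))
  }
  hits[, dist := abs(pos5 - tsspos)]
  # upstream tie-break: the gene whose TSS lies downstream of the read
  hits[, upstream_rank := fifelse(strand == "+", tsspos, -tsspos)]
  setorder(hits, ridx, dist, upstream_rank)
  hits <- hits[!duplicated(ridx)]
  hits[, offset5 := fifelse(strand == "+", pos5 - tsspos, tsspos - pos5)]
  hits[, offset3 := fifelse(strand == "+", pos3 - tsspos, tsspos - pos3)]
  hits[, .(gene_id, occurrence, offset5, offset3, len)]
}

#' RNA length by initiation position
#'
#' Mean and SEM of read length at each gene-oriented initiation offset from
#' the final TSS, after dropping reads longer than `max_len` (reads longer
#' than the maximal adapter-trimmable insert are not represented in
#' length-based analyses).
#'
#' @param assigned Assigned reads ([assign_reads_to_genes()]).
#' @param max_len Maximum representable read length (default 47 nt).
#' @return `data.table` with `offset5`, `n_reads`, `mean_length`,
#'   `sem_length`; offsets with no reads are absent. The number of
#'   over-length reads dropped is reported via `message()`.
#' @export
length_by_initiation <- function(assigned, max_len = 47L) {
  long <- assigned$len > max_len
  if (any(long)) message(sum(long), " reads longer than ", max_len,
                         " nt dropped from length analysis")
  x <- assigned[!long]
  out <- x[, .(n_reads = .N, mean_length = mean(len),
               sem_length = sd(len) / sqrt(.N)), by = offset5]
  setorder(out, offset5)
  out[]
}

#' Initiation-class 5'/3' profiles and the anchored-shift statistic
#'
#' Classifies reads by their 5' offset from the final TSS into an upstream
#' band and a downstream band (the band between them, around the TSS itself,
#' is excluded), then builds per-class 5'- and 3'-end metaprofiles. The shift
#' statistic is the difference of class 3'-end centroids (downstream minus
#' upstream): if pausing is anchored to the initiation position it equals the
#' gap between the class 5' centroids; if pausing is pinned to the DNA
#' sequence it is ~ 0. Per-class 3' profile peak offsets are also reported.
#'
#' @param assigned Assigned reads ([assign_reads_to_genes()]).
#' @param upstream,downstream Inclusive 5'-offset bands (defaults
#'   `c(-10, -5)` and `c(5, 40)`).
#' @param flank Profile extent (offsets `-flank .. +flank`, default 150).
#' @param min_reads Classes with fewer reads are flagged underpowered and
#'   excluded from the shift statistic (default 100).
#' @param max_len Drop reads longer than this before profiling (default 47).
#' @return List of class `initiation_classes`: per-class list (`n`,
#'   `centroid5`, `centroid3`, `peak3`, `profile5`, `profile3`,
#'   `underpowered`), plus `shift_statistic`, `centroid_gap` (downstream -
#'   upstream 5' centroids) and `offsets`.
#' @export
initiation_class_profiles <- function(assigned, upstream = c(-10L, -5L),
                                      downstream = c(5L, 40L), flank = 150L,
                                      min_reads = 100L, max_len = 47L) {
  stopifnot(upstream[1] <= upstream[2], downstream[1] <= downstream[2],
            upstream[2] < downstream[1])
  x <- assigned[len <= max_len]
  offsets <- seq.int(-flank, flank)
  classes <- list(
    upstream = x[offset5 >= upstream[1] & offset5 <= upstream[2]],
    downstream = x[offset5 >= downstream[1] & offset5 <= downstream[2]]
  )
  per_class <- lapply(classes, function(cl) {
    n <- nrow(cl)
    prof5 <- tabulate_offsets(cl$offset5, flank)
    prof3 <- tabulate_offsets(cl$offset3, flank)
    list(n = n,
         centroid5 = if (n) mean(cl$offset5) else NA_real_,
         centroid3 = if (n) mean(cl$offset3) else NA_real_,
         peak3 = profile_peak_offset(prof3, offsets),
         profile5 = prof5, profile3 = prof3,
         underpowered = n < min_reads)
  })
  ok <- !per_class$upstream$underpowered && !per_class$downstream$underpowered
  shift <- if (ok)
    per_class$downstream$centroid3 - per_class$upstream$centroid3 else NA_real_
  gap <- if (ok)
    per_class$downstream$centroid5 - per_class$upstream$centroid5 else NA_real_
  structure(list(classes = per_class, shift_statistic = shift,
                 centroid_gap = gap, offsets = offsets,
                 upstream = upstream, downstream = downstream),
            class = "initiation_classes")
}

tabulate_offsets <- function(off, flank) {
  off <- off[off >= -flank & off <= flank]
  counts <- tabulate(off + flank + 1L, nbins = 2L * flank + 1L)
  names(counts) <- seq.int(-flank, flank)
  counts
}

#' @export
print.initiation_classes <- function(x, ...) {
  cat(sprintf(
    "<initiation_classes> upstream [%d,%d] n=%d, downstream [%d,%d] n=%d | shift %.2f nt (5' centroid gap %.2f nt)\n",
    x$upstream[1], x$upstream[2], x$classes$upstream$n,
    x$downstream[1], x$downstream[2], x$classes$downstream$n,
    x$shift_statistic, x$centroid_gap))
  invisible(x)
}
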