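# Non-genic initiation element discovery: strand-specific greedy summit
# calling on 5'-end coverage (a documented stand-in for an external
# factor-style peak caller; an external peak BED is also accepted), exclusion
# of promoter-proximal peaks (+/- 3 kb of any known or assembled TSS), and
# merging of nearby peaks into bidirectional regions when at least two
# adjacent peaks sit on opposite strands -- the short unstable two-strand
# initiation signature of active enhancers.

#' Greedy strand-specific peak calling on 5'-end coverage
#'
#' Candidate summits are all positions with `count >= min_count`, visited in
#' descending count order (position ascending at ties, for determinism); a
#' summit is accepted if it lies at least `min_separation` nt from every
#' previously accepted summit on the same strand and chromosome. Each peak's
#' interval is the maximal run of consecutive non-zero positions through the
#' summit, truncated to +/- `min_separation`.
#'
#' @param cov5 5'-end `end_coverage`.
#' @param min_count Minimum summit count (default 10).
#' @param min_separation Minimum distance between same-strand summits
#'   (default 150 nt).
#' @return `data.table`: `peak_id`, `chrom`, `strand`, `summit`,
#'   `summit_count`, `start`, `end` (0-based half-open support interval).
#' @export
call_strand_peaks <- function(cov5, min_count = 10L, min_separation = 150L) {
  cand <- cov5$counts[count >= min_count]
  if (nrow(cand) == 0L) return(empty_peaks())
  setorder(cand, chrom, strand, -count, pos)
  res <- cand[, {
    acc <- integer(0); acc_count <- integer(0)
    for (k in seq_len(.N)) {
      p <- pos[k]
      if (!length(acc) || all(abs(acc - p) >= min_separation)) {
        acc <- c(acc, p); acc_count <- c(acc_count, count[k])
      }
    }
    .(summit = acc, summit_count = acc_count)
  }, by = .(chrom, strand)]
  # support interval: consecutive nonzero run through the summit
  all_pos <- cov5$counts[count > 0L, .(chrom, strand, pos)]
  setkey(all_pos, chrom, strand, pos)
  res[, c("start", "end") := {
    runs <- mapply(function(ch, st, sm) {
      win <- all_pos[.(ch, st)][pos >= sm - min_separation &
                                  pos <= sm + min_separation, pos]
      lo <- sm
      while ((lo - 1L) %in% win) lo <- lo - 1L
      hi <- sm
      while ((hi + 1L) %in% win) hi <- hi + 1L
      c(lo, hi + 1L)
    }, chrom, strand, summit)
    list(as.integer(runs[1L, ]), as.integer(runs[2L, ]))
  }]
  setorder(res, chrom, summit, strand)
  res[, peak_id := sprintf("peak_%05d", .I)]
  setcolorder(res, c("peak_id", "chrom", "strand", "summit", "summit_count",
                     "start", "end"))
  res[]
}

empty_peaks <- function() {
  data.table(peak_id = character(), chrom = character(), strand = character(),
             summit = integer(), summit_count = integer(),
             start = integer(), end = integer())
}

#' Load peaks from an external BED6 file
#'
#' Accepts peaks called by an external tool so the downstream filter/merge
#' stages can be reproduced exactly. The interval midpoint is used as the
#' summit; the score column as the summit count.
#'
#' @param path BED6 file.
#' @return Peak table as from [call_strand_peaks()].
#' @export
load_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("peaks must be stranded: ", path)
  out <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    summit_count = if (!is.null(gr$score)) as.integer(gr$score) else NA_integer_
  )
  out[, summit := start + (end - 1L - start) %/% 2L]
  setorder(out, chrom, summit, strand)
  out[, peak_id := sprintf("peak_%05d", .I)]
  setcolorder(out, c("peak_id", "chrom", "strand", "summit", "summit_count",
                     "start", "end"))
  out[]
}

#' Remove promoter-proximal peaks
#'
#' Drops every peak whose summit lies within +/- `exclusion` nt (inclusive)
#' of any TSS, strand-agnostic. The TSS list should combine annotated gene
#' TSSs with assembled-transcript TSSs when available.
#'
#' @param peaks Peak table.
#' @param tss_list `data.table` with `chrom`, `pos` (0-based TSS positions).
#' @param exclusion Half-width of the excluded promoter region (default
#'   3000 nt).
#' @return Filtered peak table.
#' @export
filter_promoter_proximal <- function(peaks, tss_list, exclusion = 3000L) {
  if (nrow(peaks) == 0L || nrow(tss_list) == 0L) return(copy(peaks))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$summit + 1L, width = 1L)),
    GenomicRanges::GRanges(tss_list$chrom,
                           IRanges::IRanges(tss_list$pos + 1L - exclusion,
                                            tss_list$pos + 1L + exclusion)),
    ignore.strand = TRUE
  )
  drop <- unique(S4Vectors::queryHits(hits))
  message(length(drop), " promoter-proximal peaks removed")
  if (length(drop)) peaks[-drop] else copy(peaks)
}

#' Merge peaks into bidirectional regions
#'
#' Chains peaks (per chromosome, in summit order) whose consecutive summits
#' are at most `max_gap` nt apart; each maximal chain of 2 or more peaks that
#' contains at least one adjacent opposite-strand pair becomes a
#' bidirectional region spanning its members' support intervals.
#'
#' @param peaks Peak table ([call_strand_peaks()] / [load_peaks_bed()]).
#' @param max_gap Maximum summit-to-summit gap inside a chain (default
#'   3000 nt).
#' @return `data.table`: `region_id`, `chrom`, `start`, `end`, `n_peaks`,
#'   `n_plus`, `n_minus`, `members` (comma-separated peak ids).
#' @export
merge_bidirectional <- function(peaks, max_gap = 3000L) {
  if (nrow(peaks) == 0L) return(empty_regions())
  p <- copy(peaks)
  setorder(p, chrom, summit, strand)
  p[, chain := cumsum(c(TRUE, chrom[-1L] != chrom[-.N] |
                          summit[-1L] - summit[-.N] > max_gap))]
  regions <- p[, {
    adj_opposite <- .N >= 2L && any(strand[-1L] != strand[-.N])
    if (.N >= 2L && adj_opposite) {
      .(start = min(start), end = max(end), n_peaks = .N,
        n_plus = sum(strand == "+"), n_minus = sum(strand == "-"),
        members = paste(peak_id, collapse = ","))
    } else NULL
  }, by = .(chain, chrom)][, chain := NULL]
  if (nrow(regions) == 0L) return(empty_regions())
  setorder(regions, chrom, start)
  regions[, region_id := sprintf("bidir_%04d", .I)]
  setcolorder(regions, c("region_id", "chrom", "start", "end", "n_peaks",
                         "n_plus", "n_minus", "members"))
  regions[]
}

empty_regions <- function() {
  data.table(region_id = character(), chrom = character(), start = integer(),
             end = integer(), n_peaks = integer(), n_plus = integer(),
             n_minus = integer(), members = character())
}

#' Select novel intergenic multi-exon transcripts
#'
#' A transcript from an assembly GTF is novel-intergenic iff none of its
#' exons overlaps any known gene body by any base (strand-agnostic); of
#' those, only transcripts with 2 or more exons are retained as candidate new
#' genes (single-exon assemblies are over-reported by short-read assemblers).
#'
#' @param assembled_gtf Path to the assembled-transcript GTF (exon features).
#' @param known_gtf Path to the known-gene GTF (gene bodies; gene features
#'   when present, else the per-gene span of its records).
#' @return List: `transcripts` (`data.table` with `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_exons`, `intergenic`, `retained`),
#'   `n_intergenic`, `n_multi_exon` and `multi_exon_fraction` over the
#'   intergenic set.
#' @export
select_novel_transcripts <- function(assembled_gtf, known_gtf) {
  asm <- rtracklayer::import(assembled_gtf, format = "gtf")
  exons <- asm[as.character(asm$type) == "exon"]
  if (length(exons) == 0L) stop("no exon features in ", assembled_gtf)
  no_tx <- is.na(exons$transcript_id)
  if (any(no_tx)) {
    warning(sum(no_tx), " exon(s) without transcript_id skipped")
    exons <- exons[!no_tx]
  }
  known <- rtracklayer::import(known_gtf, format = "gtf")
  ktype <- as.character(known$type)
  bodies <- if (any(ktype == "gene")) known[ktype == "gene"] else {
    unlist(range(GenomicRanges::split(known, known$gene_id), ignore.strand = TRUE))
  }
  hit_exons <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(exons, bodies, ignore.strand = TRUE)))
  exon_dt <- data.table(
    transcript_id = as.character(exons$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(exons)),
    strand = as.character(BiocGenerics::strand(exons)),
    start = BiocGenerics::start(exons) - 1L,
    end = BiocGenerics::end(exons),
    overlaps = seq_along(exons) %in% hit_exons
  )
  tx <- exon_dt[, .(chrom = chrom[1L], strand = strand[1L],
                    start = min(start), end = max(end), n_exons = .N,
                    intergenic = !any(overlaps)), by = transcript_id]
  tx[, retained := intergenic & n_exons >= 2L]
  setorder(tx, chrom, start)
  n_intergenic <- sum(tx$intergenic)
  n_multi <- sum(tx$retained)
  message(sprintf(
    "%d intergenic transcripts, %d (%.1f%%) multi-exon retained as novel",
    n_intergenic, n_multi,
    if (n_intergenic) 100 * n_multi / n_intergenic else 0))
  list(transcripts = tx[], n_intergenic = n_intergenic,
       n_multi_exon = n_multi,
       multi_exon_fraction = if (n_intergenic) n_multi / n_intergenic else NA_real_)
}

#' Write peaks or regions as BED6
#'
#' @param x Peak or region table.
#' @param path Output path.
#' @export
write_elements_bed <- function(x, path) {
  if ("summit" %in% names(x)) {
    bed <- data.table(x$chrom, x$start, x$end, x$peak_id, x$summit_count,
                      x$strand)
  } else {
    bed <- data.table(x$chrom, x$start, x$end, x$region_id, x$n_peaks, ".")
  }
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
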