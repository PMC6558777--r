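# Readers/writers for the standard formats the pipeline touches.
# One internal coordinate convention everywhere: 0-based, half-open intervals;
# a TSS is the single 0-based position of the initiating base (interval start
# on the plus strand, interval end - 1 on the minus strand). GTF input
# (1-based, closed) is converted on load; BED passes through unchanged.

#' Load a gene annotation as one TSS per record
#'
#' Reads a GTF (1-based closed, converted on load) or BED (0-based half-open)
#' gene annotation and returns one record per annotated start site. Records
#' sharing a `gene_id` but with distinct TSSs are retained as distinct
#' analysis units and tagged with an occurrence index; with `dedupe = TRUE`
#' exact duplicates of the same `(gene_id, tss)` pair are collapsed to one.
#'
#' @param path Path to a GTF/GFF (`.gtf`, `.gff`, `.gff3`) or BED file.
#'   GTF files use `gene` features when present, otherwise `transcript`
#'   features; BED uses the name column as `gene_id`.
#' @param dedupe Collapse records with identical `(gene_id, chrom, strand,
#'   tss)` to a single entry (default `TRUE`).
#' @return A `data.table` with columns `gene_id`, `occurrence`, `chrom`,
#'   `strand`, `tss`, `body_start`, `body_end` (0-based half-open).
#'   Records without a strand are dropped with a warning.
#' @export
load_gene_annotation <- function(path, dedupe = TRUE) {
  fmt <- annotation_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gtf") {
    type <- as.character(gr$type)
    keep_type <- if (any(type == "gene")) "gene" else "transcript"
    gr <- gr[type == keep_type]
    ids <- as.character(gr$gene_id)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("record_", seq_along(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  no_strand <- !strand %in% c("+", "-")
  if (any(no_strand)) {
    warning(sum(no_strand), " record(s) without strand dropped from ", path)
    gr <- gr[!no_strand]; ids <- ids[!no_strand]; strand <- strand[!no_strand]
  }
  if (any(is.na(ids) | !nzchar(ids))) stop("gene records with empty gene_id in ", path)
  genes <- data.table(
    gene_id    = ids,
    chrom      = as.character(GenomeInfoDb::seqnames(gr)),
    strand     = strand,
    body_start = BiocGenerics::start(gr) - 1L,  # to 0-based
    body_end   = BiocGenerics::end(gr)          # closed end -> half-open end
  )
  genes[, tss := fifelse(strand == "+", body_start, body_end - 1L)]
  if (dedupe) genes <- unique(genes, by = c("gene_id", "chrom", "strand", "tss"))
  setorder(genes, gene_id, chrom, tss)
  genes[, occurrence := seq_len(.N), by = gene_id]
  setcolorder(genes, c("gene_id", "occurrence", "chrom", "strand", "tss",
                       "body_start", "body_end"))
  setorder(genes, chrom, tss)
  genes[]
}

annotation_format <- function(path) {
  if (grepl("\\.g[tf]f3?$", path, ignore.case = TRUE)) "gtf" else "bed"
}

#' Load stranded aligned reads from BED6
#'
#' @param path BED6 file of aligned read intervals.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `name` in input order (0-based half-open). Reads with strand `.` are
#'   rejected with a warning; `start >= end` is a hard error.
#' @export
load_reads <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0L) {
    warning("no reads loaded from ", path)
    return(empty_reads())
  }
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) warning(sum(bad), " read(s) without strand rejected from ", path)
  gr <- gr[!bad]; strand <- strand[!bad]
  reads <- data.table(
    chrom  = as.character(GenomeInfoDb::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,
    end    = BiocGenerics::end(gr),
    strand = strand,
    name   = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("read_", seq_along(gr))
  )
  if (any(reads$start >= reads$end)) stop("read with start >= end in ", path)
  message(nrow(reads), " reads loaded from ", path)
  reads[]
}

empty_reads <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character())
}

#' Write reads as BED6
#'
#' @param reads Read table as returned by [load_reads()].
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  bed <- data.table(reads$chrom, reads$start, reads$end,
                    if (is.null(reads$name)) "." else reads$name,
                    0L, reads$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Load a BED file of intervals (e.g. a contaminant blacklist)
#'
#' @param path BED file.
#' @return Normalized interval `data.table` (`chrom`, `start`, `end`),
#'   sorted and merged so intervals are per-chromosome non-overlapping.
#' @export
load_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  normalize_intervals(data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr)
  ))
}

#' Normalize an interval set
#'
#' Sorts intervals and merges overlapping ones per chromosome
#' (strand-agnostic), yielding the canonical form used for masks.
#'
#' @param intervals `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Normalized `data.table`.
#' @export
normalize_intervals <- function(intervals) {
  stopifnot(all(intervals$start < intervals$end))
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals), ignore.strand = TRUE)
  out <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr)
  )
  setorder(out, chrom, start)
  out[]
}

# 0-based half-open table -> 1-based closed GRanges
intervals_to_granges <- function(x, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (is.null(strand)) "*" else strand
  )
}

#' Remove reads overlapping a blacklist mask
#'
#' A read is removed iff any of its bases overlaps any mask interval,
#' regardless of strand. Idempotent and independent of read order.
#'
#' @param reads Read table ([load_reads()]).
#' @param mask Normalized interval table ([normalize_intervals()]).
#' @return Filtered read table; removal count reported via `message()`.
#' @export
filter_blacklist <- function(reads, mask) {
  if (nrow(reads) == 0L || nrow(mask) == 0L) return(copy(reads))
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(reads), intervals_to_granges(mask),
    ignore.strand = TRUE
  )
  drop <- unique(S4Vectors::queryHits(hits))
  message(length(drop), " reads removed by blacklist")
  if (length(drop)) reads[-drop] else copy(reads)
}

#' Write single-strand end coverage as bedGraph
#'
#' Emits sorted bedGraph records with adjacent equal-value runs merged;
#' [read_bedgraph()] reconstructs the coverage exactly.
#'
#' @param cov A [build_end_coverage()] object.
#' @param strand `"+"` or `"-"`; which strand's counts to write.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, strand, path) {
  stopifnot(inherits(cov, "end_coverage"), strand %in% c("+", "-"))
  x <- cov$counts[strand, on = "strand", nomatch = NULL]
  if (nrow(x) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  setorder(x, chrom, pos)
  x[, run := cumsum(!(chrom == shift(chrom, fill = "") &
                        pos == shift(pos, fill = -2L) + 1L &
                        count == shift(count, fill = -1L)))]
  runs <- x[, .(chrom = chrom[1L], start = pos[1L], end = pos[.N] + 1L,
                value = count[1L]), by = run][, run := NULL]
  fwrite(runs, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into sparse counts
#'
#' @param path bedGraph file.
#' @param strand Strand label to attach to the counts.
#' @param end_kind `"five_prime"` or `"three_prime"` label for the coverage.
#' @return An `end_coverage` object holding the file's counts on one strand.
#' @export
read_bedgraph <- function(path, strand, end_kind = "five_prime") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(new_end_coverage(empty_counts(), end_kind, 0L))
  runs <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr),
    value = as.integer(gr$score)
  )
  runs[, idx := .I]
  counts <- runs[, .(chrom = chrom, pos = seq.int(start, end - 1L),
                     count = value), by = idx][, idx := NULL]
  counts[, strand := strand]
  setcolorder(counts, c("chrom", "strand", "pos", "count"))
  setkey(counts, chrom, strand, pos)
  new_end_coverage(counts, end_kind, sum(counts$count))
}

#' Write a genome as FASTA
#'
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Load a genome FASTA
#'
#' @param path FASTA file.
#' @return Named `DNAStringSet`.
#' @export
load_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
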