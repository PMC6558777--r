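# Strand-aware sequence context extraction around called positions, position
# frequency matrices and per-position information content. Used for the
# initiator (Inr) motif check at reannotated TSSs and the G/C preference at
# RNA 3' ends. Uniform background, no pseudocounts, no small-sample
# correction; ambiguous bases are excluded per offset, not per sequence.

#' Extract strand-aware sequence contexts
#'
#' Returns the `2 * flank + 1` nt sequence centered on each anchor, with
#' minus-strand anchors reverse-complemented so the center base is the
#' template-directed initiation (or pause) base. Anchors whose window leaves
#' the chromosome, or on unknown chromosomes, are skipped with a warning.
#'
#' @param genome Named `DNAStringSet` ([load_genome_fasta()]).
#' @param chrom,pos,strand Parallel anchor vectors (0-based positions).
#' @param flank Context half-width in nt (default 15).
#' @return Character vector of contexts (one per retained anchor).
#' @export
extract_contexts <- function(genome, chrom, pos, strand, flank = 15L) {
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  known <- chrom %in% names(genome)
  if (any(!known)) warning(sum(!known), " anchors on unknown chromosomes skipped")
  inb <- known & pos - flank >= 0L & pos + flank < chrlen[chrom]
  if (any(known & !inb)) warning(sum(known & !inb), " out-of-bounds anchors skipped")
  chrom <- chrom[inb]; pos <- pos[inb]; strand <- strand[inb]
  if (length(pos) == 0L) return(character())
  seqs <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    v <- Biostrings::Views(genome[[ch]], start = pos[i] - flank + 1L,
                           end = pos[i] + flank + 1L)
    s <- as.character(v)
    minus <- strand[i] == "-"
    if (any(minus)) {
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    }
    seqs[i] <- s
  }
  seqs
}

#' Position frequency matrix of equal-length sequences
#'
#' Counts A/C/G/T per offset; bases outside ACGT (e.g. N) are excluded at
#' that offset only.
#'
#' @param seqs Character vector of equal-length sequences whose center base
#'   is the anchor.
#' @return List of class `pfm`: `counts` (4 x width matrix, rows A,C,G,T,
#'   columns named by offset), `n_sequences`.
#' @export
pfm_from_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  counts <- matrix(0L, nrow = 4L, ncol = w,
                   dimnames = list(c("A", "C", "G", "T"),
                                   seq.int(-(w %/% 2L), w %/% 2L)))
  present <- intersect(rownames(m), rownames(counts))
  counts[present, ] <- m[present, ]
  structure(list(counts = counts, n_sequences = length(seqs)), class = "pfm")
}

#' Per-offset information content of a PFM
#'
#' `IC(o) = 2 + sum_b f_b(o) * log2 f_b(o)` against a uniform background,
#' with `0 * log 0 = 0` and no small-sample correction. Ranges from 0 bits
#' (uniform) to 2 bits (a single base).
#'
#' @param pfm A [pfm_from_sequences()] object (or a 4 x width count matrix).
#' @return Named numeric vector of bits per offset.
#' @export
pfm_information_content <- function(pfm) {
  counts <- if (inherits(pfm, "pfm")) pfm$counts else pfm
  apply(counts, 2L, function(cl) {
    tot <- sum(cl)
    if (tot == 0L) return(NA_real_)
    f <- cl / tot
    nz <- f > 0
    2 + sum(f[nz] * log2(f[nz]))
  })
}

#' Sequence context and G/C preference at RNA 3' ends
#'
#' PFM anchored on each read's own 3'-end base (strand-aware), plus the
#' fraction of G or C at offset 0 — pause positions preferring G/C show this
#' fraction above the genome background.
#'
#' @param genome Named `DNAStringSet`.
#' @param chrom,pos,strand Parallel vectors of 3'-end positions (0-based).
#' @param flank Context half-width (default 15 nt).
#' @return List: `pfm`, `ic` (per-offset bits), `gc_at_zero`.
#' @export
three_prime_context <- function(genome, chrom, pos, strand, flank = 15L) {
  seqs <- extract_contexts(genome, chrom, pos, strand, flank = flank)
  if (length(seqs) == 0L) return(list(pfm = NULL, ic = NULL, gc_at_zero = NA_real_))
  pfm <- pfm_from_sequences(seqs)
  center <- pfm$counts[, as.character(0)]
  gc <- (center["G"] + center["C"]) / sum(center)
  list(pfm = pfm, ic = pfm_information_content(pfm), gc_at_zero = unname(gc))
}

#' G/C fraction of a genome
#'
#' @param genome Named `DNAStringSet`.
#' @return Fraction of G+C among A/C/G/T bases.
#' @export
genome_gc_fraction <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                     drop = FALSE])
  unname((f["C"] + f["G"]) / sum(f))
}

#' Write a PFM and its information content as TSV
#'
#' @param pfm A [pfm_from_sequences()] object.
#' @param path Output path.
#' @export
write_pfm_tsv <- function(pfm, path) {
  ic <- pfm_information_content(pfm)
  out <- data.table(offset = as.integer(colnames(pfm$counts)),
                    A = pfm$counts["A", ], C = pfm$counts["C", ],
                    G = pfm$counts["G", ], T = pfm$counts["T", ],
                    ic_bits = ic)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
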