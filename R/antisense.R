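# Divergent and convergent antisense TSS calling. Both scan the strand
# opposite to the gene within 500 bp of the (reannotated) sense TSS:
# divergent initiation upstream of the promoter, directed away from the gene;
# convergent initiation downstream, directed back at the promoter. Offset 0
# (directly opposite the sense TSS) belongs to neither window, keeping the
# two searches disjoint.

#' Call the divergent or convergent antisense TSS of one gene
#'
#' Scans opposite-strand 5'-end signal at gene-oriented offsets
#' `[-window, -1]` (divergent) or `[+1, +window]` (convergent) from the sense
#' TSS. No call is made when the opposite-strand window total is below the
#' noise threshold. Ties at equal counts go to the offset nearest the sense
#' TSS.
#'
#' @param cov5 5'-end `end_coverage`.
#' @param gene_tss 0-based sense TSS position (reannotated when available).
#' @param gene_chrom Chromosome.
#' @param gene_strand Gene strand.
#' @param kind `"divergent"` or `"convergent"`.
#' @param window Search extent in nt (default 500).
#' @param threshold Minimum opposite-strand window total (default 10).
#' @return One-row `data.table` (`kind`, `peak_position`, `peak_offset`,
#'   `peak_count`, `window_total`) or `NULL` when below threshold.
#' @export
call_antisense_tss <- function(cov5, gene_tss, gene_chrom, gene_strand,
                               kind = c("divergent", "convergent"),
                               window = 500L, threshold = 10L) {
  kind <- match.arg(kind)
  gene <- data.table(gene_id = "g", occurrence = 1L, chrom = gene_chrom,
                     strand = gene_strand, pos = gene_tss)
  out <- antisense_table(cov5, gene, kinds = kind, window = window,
                         threshold = threshold, flank = NULL)
  if (nrow(out) == 0L) NULL else
    out[, .(kind, peak_position, peak_offset, peak_count, window_total)]
}

#' Antisense TSS calls for a table of genes
#'
#' Vectorized [call_antisense_tss()] over a final-TSS anchor table, with the
#' +/- `flank` nt antisense-strand count around each called peak attached
#' (the quantity used for sense/antisense correlations).
#'
#' @param cov5 5'-end `end_coverage`.
#' @param tss_table Anchor table ([final_tss_table()]): `gene_id`,
#'   `occurrence`, `chrom`, `strand`, `pos`.
#' @param kinds Which calls to make (default both).
#' @param window Search extent (default 500 nt).
#' @param threshold Opposite-strand window-total noise threshold (default 10).
#' @param flank Half-width of the peak-anchored count (default 50 nt);
#'   `NULL` skips it.
#' @return `data.table`, one row per (gene, kind) that passed the threshold:
#'   `gene_id`, `occurrence`, `kind`, `peak_position`, `peak_offset` (signed,
#'   gene orientation), `peak_count`, `flank50`, `window_total`.
#' @export
antisense_table <- function(cov5, tss_table,
                            kinds = c("divergent", "convergent"),
                            window = 500L, threshold = 10L, flank = 50L) {
  res <- rbindlist(lapply(kinds, function(k) {
    hits <- window_hits_batch(cov5, tss_table, up = window, down = window,
                              query_strand = "opposite")
    hits <- if (k == "divergent") hits[offset <= -1L & offset >= -window]
            else hits[offset >= 1L & offset <= window]
    if (nrow(hits) == 0L) return(NULL)
    hits[, abs_off := abs(offset)]
    setorder(hits, idx, -count, abs_off)
    calls <- hits[, .(peak_offset = offset[1L], peak_count = count[1L],
                      window_total = sum(count)), by = idx]
    calls <- calls[window_total >= threshold]
    if (nrow(calls) == 0L) return(NULL)
    calls[, kind := k]
    calls
  }))
  if (is.null(res) || nrow(res) == 0L) return(empty_antisense_table())
  g <- tss_table[res$idx]
  out <- data.table(
    gene_id = g$gene_id, occurrence = g$occurrence, kind = res$kind,
    chrom = g$chrom, gene_strand = g$strand,
    peak_position = fifelse(g$strand == "+", g$pos + res$peak_offset,
                            g$pos - res$peak_offset),
    peak_offset = res$peak_offset,
    peak_count = res$peak_count,
    window_total = res$window_total
  )
  if (!is.null(flank)) {
    anti <- data.table(chrom = out$chrom,
                       strand = fifelse(out$gene_strand == "+", "-", "+"),
                       pos = out$peak_position)
    out[, flank50 := window_counts_batch(cov5, anti, up = flank, down = flank,
                                         query_strand = "same")]
  }
  setorder(out, gene_id, occurrence, kind)
  out[]
}

empty_antisense_table <- function() {
  data.table(gene_id = character(), occurrence = integer(), kind = character(),
             chrom = character(), gene_strand = character(),
             peak_position = integer(), peak_offset = integer(),
             peak_count = integer(), window_total = integer(),
             flank50 = integer())
}

#' Peak-anchored antisense count (+/- flank nt)
#'
#' Inclusive +/- `flank` nt sum of 5'-end signal on the given strand around a
#' called antisense peak.
#'
#' @param cov5 5'-end `end_coverage`.
#' @param chrom Chromosome.
#' @param peak_position Called peak position (0-based).
#' @param strand Strand carrying the antisense signal.
#' @param flank Half-width in nt (default 50).
#' @return Integer count.
#' @export
flank50_count <- function(cov5, chrom, peak_position, strand, flank = 50L) {
  window_count(cov5, chrom, strand, peak_position, up = flank, down = flank)
}

#' Spearman correlation matrix of sense and antisense signal
#'
#' Pairwise Spearman correlations over a gene-aligned matrix of counts
#' (e.g. sense window counts and divergent/convergent peak-flank counts per
#' replicate). Genes lacking a call contribute `NA` and are dropped pairwise;
#' cells with fewer than 3 complete pairs are `NA`.
#'
#' @param counts Numeric matrix or data.frame, genes x signal columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
antisense_correlation_matrix <- function(counts) {
  m <- as.matrix(counts)
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(out) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      rho <- spearman_rho(m[, i], m[, j])
      out[i, j] <- out[j, i] <- rho
    }
  }
  out
}
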