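# Base-pair TSS reannotation from 5'-end coverage: per-gene sense-strand peak
# call within +/- window of the annotated TSS, a read-count noise filter
# applied across replicates, a per-replicate normal fit of peak offsets, and
# a 1-SD distance filter. Genes passing all filters get their TSS reassigned
# to the peak position of the primary (highest-coverage) replicate.

#' Per-gene sense-strand 5'-end peak call
#'
#' Finds the position with the largest number of sense-strand read 5' ends
#' within `annotated TSS +/- window`. Ties are broken by smallest absolute
#' offset, then upstream (5'-most in gene orientation).
#'
#' @param cov5 5'-end `end_coverage`.
#' @param gene A single-row gene record (`chrom`, `strand`, `tss`).
#' @param window Half-window in nt (default 500).
#' @return List with `peak_tss`, `peak_offset` (signed, gene orientation,
#'   positive = downstream), `peak_count`, `window_count`; `peak_tss` is `NA`
#'   when the window holds no signal.
#' @export
call_peak_position <- function(cov5, gene, window = 500L) {
  stopifnot(window > 0L)
  calls <- call_peaks_batch(
    cov5,
    data.table(chrom = gene$chrom, strand = gene$strand, pos = gene$tss),
    window = window
  )
  as.list(calls[1L, .(peak_tss, peak_offset, peak_count, window_count_)])
}

# Vectorized peak call for a table of anchors (chrom, strand, pos).
call_peaks_batch <- function(cov5, anchors, window = 500L,
                             query_strand = "same") {
  hits <- window_hits_batch(cov5, anchors, up = window, down = window,
                            query_strand = query_strand)
  base <- data.table(idx = seq_len(nrow(anchors)))
  if (nrow(hits) == 0L) {
    out <- base[, .(idx, peak_offset = NA_integer_, peak_count = NA_integer_,
                    window_count_ = 0L)]
  } else {
    hits[, abs_off := abs(offset)]
    setorder(hits, idx, -count, abs_off, offset)
    best <- hits[, .(peak_offset = offset[1L], peak_count = count[1L],
                     window_count_ = sum(count)), by = idx]
    out <- best[base, on = "idx"]
    out[is.na(window_count_), `:=`(window_count_ = 0L)]
  }
  out[, peak_tss := fifelse(anchors$strand == "+",
                            anchors$pos + peak_offset,
                            anchors$pos - peak_offset)]
  out[]
}

#' Noise filter across replicates
#'
#' A gene passes only if its sense-strand window count reaches the threshold
#' in every replicate ("fewer than N reads in either replicate" fails).
#'
#' @param counts_by_rep Matrix or data.frame of window counts, genes x
#'   replicates.
#' @param threshold Minimum reads per replicate (default 10).
#' @return Logical vector, one entry per gene.
#' @export
noise_filter <- function(counts_by_rep, threshold = 10L) {
  m <- as.matrix(counts_by_rep)
  apply(m, 1L, function(r) all(r >= threshold))
}

#' Fit a normal distribution to peak offsets
#'
#' Sample mean and standard deviation (denominator n - 1) of the signed
#' peak offsets of noise-passing genes; fitted per replicate.
#'
#' @param offsets Signed offsets in nt (gene orientation).
#' @return List `mean`, `sd`, `n`. Fewer than 2 offsets or zero spread is a
#'   degenerate fit and raises an error.
#' @export
fit_offset_distribution <- function(offsets) {
  offsets <- offsets[!is.na(offsets)]
  if (length(offsets) < 2L) stop("offset fit needs at least 2 offsets")
  s <- sd(offsets)
  if (s == 0) stop("degenerate offset fit: zero standard deviation")
  list(mean = mean(offsets), sd = s, n = length(offsets))
}

#' Distance filter against an offset fit
#'
#' A call passes iff `|offset - mean| <= sd` (boundary inclusive): the 1-SD
#' range around the fitted mean is the maximum allowed distance between the
#' observed peak and the annotated TSS.
#'
#' @param offsets Signed peak offsets.
#' @param fit A [fit_offset_distribution()] result.
#' @return Logical vector (`NA` offsets fail).
#' @export
distance_filter <- function(offsets, fit) {
  !is.na(offsets) & abs(offsets - fit$mean) <= fit$sd
}

#' Reannotate gene TSSs from 5'-end coverage
#'
#' Pipeline per the standard order of operations: per-gene sense-strand peak
#' call around the annotated TSS in every replicate; noise filter (window
#' count `>= noise_threshold` in all replicates); per-replicate normal fit of
#' peak offsets over noise-passing genes; distance filter (`|offset - mean|
#' <= sd` in all replicates). Passing genes take `final_tss` from the primary
#' replicate (by default the replicate with the larger genome-wide read
#' total).
#'
#' @param genes Gene table ([load_gene_annotation()]).
#' @param cov5_reps Named list of 5'-end `end_coverage` objects, one per
#'   replicate.
#' @param window Half-window around the annotated TSS (default 500 nt).
#' @param noise_threshold Minimum sense window count per replicate
#'   (default 10).
#' @param primary `"auto"` (replicate with most reads) or a replicate name /
#'   index.
#' @return List of class `tss_reannotation`:
#'   * `table`: per-gene `data.table` with `status`
#'     (`pass`/`fail_noise`/`fail_distance`), `final_tss`, signed `shift_nt`,
#'     exclusive `shift_class` (`identical`, `within_5`, `within_10`,
#'     `gt_10`), and per-replicate peak/window columns;
#'   * `calls`: long per-(gene, replicate) call table;
#'   * `fits`: per-replicate offset fits;
#'   * `primary`: name of the primary replicate.
#' @export
reannotate_tss <- function(genes, cov5_reps, window = 500L,
                           noise_threshold = 10L, primary = "auto") {
  stopifnot(length(cov5_reps) >= 1L)
  if (is.null(names(cov5_reps)))
    names(cov5_reps) <- paste0("rep", seq_along(cov5_reps))
  reps <- names(cov5_reps)

  anchors <- genes[, .(chrom, strand, pos = tss)]
  calls <- rbindlist(lapply(reps, function(r) {
    cb <- call_peaks_batch(cov5_reps[[r]], anchors, window = window)
    cb[, `:=`(rep_id = r, gene_id = genes$gene_id,
              occurrence = genes$occurrence)]
    cb
  }))

  wide <- dcast(calls, gene_id + occurrence ~ rep_id,
                value.var = c("peak_tss", "peak_offset", "peak_count",
                              "window_count_"))
  tab <- genes[wide, on = c("gene_id", "occurrence")]

  count_cols <- paste0("window_count__", reps)
  noise_pass <- noise_filter(tab[, ..count_cols], threshold = noise_threshold)

  fits <- lapply(reps, function(r) {
    fit_offset_distribution(tab[[paste0("peak_offset_", r)]][noise_pass])
  })
  names(fits) <- reps

  dist_pass <- rep(TRUE, nrow(tab))
  for (r in reps) {
    dist_pass <- dist_pass &
      distance_filter(tab[[paste0("peak_offset_", r)]], fits[[r]])
  }

  status <- fifelse(!noise_pass, "fail_noise",
                    fifelse(!dist_pass, "fail_distance", "pass"))

  if (identical(primary, "auto")) {
    totals <- vapply(cov5_reps, function(cv) cv$n_reads, integer(1))
    primary_rep <- reps[which.max(totals)]
  } else if (is.numeric(primary)) {
    primary_rep <- reps[primary]
  } else {
    stopifnot(primary %in% reps)
    primary_rep <- primary
  }

  tab[, status := status]
  tab[, final_tss := fifelse(status == "pass",
                             tab[[paste0("peak_tss_", primary_rep)]],
                             NA_integer_)]
  tab[, shift_nt := fifelse(strand == "+", final_tss - tss, tss - final_tss)]
  tab[, shift_class := shift_class_of(shift_nt)]

  if (all(status != "pass")) warning("no genes passed TSS reannotation filters")

  n_noise <- sum(noise_pass)
  message(sprintf(
    "TSS reannotation: %d genes, %d above noise threshold, %d passed distance filter",
    nrow(tab), n_noise, sum(status == "pass")))

  structure(list(table = tab[], calls = calls[], fits = fits,
                 primary = primary_rep, window = window,
                 noise_threshold = noise_threshold),
            class = "tss_reannotation")
}

shift_class_of <- function(shift_nt) {
  a <- abs(shift_nt)
  fifelse(is.na(a), NA_character_,
          fifelse(a == 0L, "identical",
                  fifelse(a <= 5L, "within_5",
                          fifelse(a <= 10L, "within_10", "gt_10"))))
}

#' Shift-class tallies of a reannotation table
#'
#' Cumulative tallies over passing genes: TSS identical to annotation,
#' within +/- 5 nt, within +/- 10 nt, and moved by more than 5 nt.
#'
#' @param reann A [reannotate_tss()] result (or its `$table`).
#' @return Named integer vector `identical`, `within_5`, `within_10`, `gt_5`,
#'   `pass`, `fail_noise`, `fail_distance`.
#' @export
shift_class_counts <- function(reann) {
  tab <- if (inherits(reann, "tss_reannotation")) reann$table else reann
  a <- abs(tab$shift_nt[tab$status == "pass"])
  c(identical = sum(a == 0L),
    within_5 = sum(a <= 5L),
    within_10 = sum(a <= 10L),
    gt_5 = sum(a > 5L),
    pass = sum(tab$status == "pass"),
    fail_noise = sum(tab$status == "fail_noise"),
    fail_distance = sum(tab$status == "fail_distance"))
}

#' @export
print.tss_reannotation <- function(x, ...) {
  cc <- shift_class_counts(x)
  cat(sprintf(
    "<tss_reannotation> %d genes | pass %d (identical %d, <=5nt %d, <=10nt %d, >5nt %d) | primary %s\n",
    nrow(x$table), cc["pass"], cc["identical"], cc["within_5"],
    cc["within_10"], cc["gt_5"], x$primary))
  invisible(x)
}

#' Final TSS anchor table of a reannotation
#'
#' One anchor per passing gene at the reannotated TSS (used for antisense,
#' pausing and motif stages).
#'
#' @param reann A [reannotate_tss()] result.
#' @return `data.table` with `gene_id`, `occurrence`, `chrom`, `strand`,
#'   `pos` (= final TSS), `label`.
#' @export
final_tss_table <- function(reann) {
  tab <- reann$table[status == "pass"]
  tab[, .(gene_id, occurrence, chrom, strand, pos = final_tss,
          label = paste(gene_id, occurrence, sep = "#"))]
}

#' Write reannotated TSSs as BED6 (1-nt intervals)
#'
#' @param reann A [reannotate_tss()] result.
#' @param path Output path. Score = primary-replicate peak count.
#' @export
write_tss_bed <- function(reann, path) {
  tab <- reann$table[status == "pass"]
  score <- tab[[paste0("peak_count_", reann$primary)]]
  if (is.null(score)) score <- 0L
  bed <- data.table(tab$chrom, tab$final_tss, tab$final_tss + 1L,
                    tab$gene_id, score, tab$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
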