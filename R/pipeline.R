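# One-command orchestration: reads + annotation in, every stage's tables out.
# Stages degrade gracefully -- the motif stage needs a genome, the pausing
# stage an expression table, the novel-transcript stage an assembly GTF; a
# missing optional input skips only its stage.

#' Pipeline configuration
#'
#' Paths plus every stage parameter at its standard default. Unknown
#' parameter names are rejected.
#'
#' @param reads Named character vector/list of per-replicate BED6 read paths.
#' @param annotation Gene annotation path (GTF or BED).
#' @param genome Optional genome FASTA (motif stage).
#' @param fpkm Optional expression TSV with columns `gene_id`, `fpkm`
#'   (pausing stage).
#' @param blacklist Optional BED of intervals whose reads are removed.
#' @param peaks Optional externally called peak BED (replaces the internal
#'   caller).
#' @param assembled_gtf Optional assembled-transcript GTF (novel-gene stage).
#' @param out_dir Output directory; `NULL` disables file output.
#' @param ... Stage parameter overrides: `window` (500), `noise_threshold`
#'   (10), `antisense_flank` (50), `three_prime_flank` (150), `max_len` (47),
#'   `upstream_band` (c(-10,-5)), `downstream_band` (c(5,40)),
#'   `class_min_reads` (100), `peak_min_count` (10), `peak_min_separation`
#'   (150), `promoter_exclusion` (3000), `merge_gap` (3000), `motif_flank`
#'   (15), `primary` ("auto").
#' @return Config list of class `startseq_config`.
#' @export
pipeline_config <- function(reads, annotation, genome = NULL, fpkm = NULL,
                            blacklist = NULL, peaks = NULL,
                            assembled_gtf = NULL, out_dir = NULL, ...) {
  defaults <- list(
    window = 500L, noise_threshold = 10L, antisense_flank = 50L,
    three_prime_flank = 150L, max_len = 47L,
    upstream_band = c(-10L, -5L), downstream_band = c(5L, 40L),
    class_min_reads = 100L, peak_min_count = 10L, peak_min_separation = 150L,
    promoter_exclusion = 3000L, merge_gap = 3000L, motif_flank = 15L,
    primary = "auto"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown pipeline parameters: ",
                            paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, overrides)
  structure(c(list(reads = reads, annotation = annotation, genome = genome,
                   fpkm = fpkm, blacklist = blacklist, peaks = peaks,
                   assembled_gtf = assembled_gtf, out_dir = out_dir),
              params),
            class = "startseq_config")
}

#' Run the full Start-seq analysis pipeline
#'
#' Loads the inputs, builds strand-specific 5'/3'-end coverage per replicate,
#' reannotates TSSs, calls divergent/convergent antisense TSSs, quantifies
#' pausing (when expression is available), profiles the initiator motif
#' context (when a genome is available), and discovers non-genic
#' bidirectional elements. All result tables are returned and, when
#' `out_dir` is set, written as TSV/BED/bedGraph alongside a manifest.
#'
#' @param config A [pipeline_config()] result.
#' @return List of class `startseq_result`: `genes`, `coverage` (per
#'   replicate, 5' and 3'), `reannotation`, `antisense`, `correlation`,
#'   `pausing`, `three_prime`, `length_by_pos`, `initiation_classes`,
#'   `motif`, `peaks`, `regions`, `novel`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "startseq_config"))
  genes <- load_gene_annotation(config$annotation)

  reads <- lapply(config$reads, load_reads)
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- paste0("rep", seq_along(reads))
  if (!is.null(config$blacklist)) {
    mask <- load_intervals(config$blacklist)
    reads <- lapply(reads, filter_blacklist, mask = mask)
  }

  cov5 <- lapply(reads, build_end_coverage, end_kind = "five_prime")
  cov3 <- lapply(reads, build_end_coverage, end_kind = "three_prime")

  reann <- reannotate_tss(genes, cov5, window = config$window,
                          noise_threshold = config$noise_threshold,
                          primary = config$primary)
  tss <- final_tss_table(reann)
  primary <- reann$primary

  anti <- antisense_table(cov5[[primary]], tss, window = config$window,
                          threshold = config$noise_threshold,
                          flank = config$antisense_flank)
  correlation <- antisense_correlation_signals(cov5, tss, anti, config)

  pausing <- three_prime <- length_by_pos <- classes <- NULL
  if (!is.null(config$fpkm)) {
    fpkm <- fread(config$fpkm)
    pausing <- pausing_table(tss, cov5[[primary]], fpkm,
                             window = config$window)
    top_q <- with(pausing, fpkm >= stats::quantile(fpkm, 0.75, na.rm = TRUE))
    three_prime <- three_prime_metaprofile(
      cov3[[primary]], tss, flank = config$three_prime_flank,
      groups = fifelse(is.na(top_q) | !top_q, "all", "top25"))
  } else {
    warning("no expression table: pausing index skipped")
    three_prime <- three_prime_metaprofile(cov3[[primary]], tss,
                                           flank = config$three_prime_flank)
  }
  assigned <- assign_reads_to_genes(reads[[primary]], tss,
                                    flank = config$three_prime_flank)
  length_by_pos <- length_by_initiation(assigned, max_len = config$max_len)
  classes <- initiation_class_profiles(
    assigned, upstream = config$upstream_band,
    downstream = config$downstream_band, flank = config$three_prime_flank,
    min_reads = config$class_min_reads, max_len = config$max_len)

  motif <- NULL
  if (!is.null(config$genome)) {
    genome <- load_genome_fasta(config$genome)
    ctx <- extract_contexts(genome, tss$chrom, tss$pos, tss$strand,
                            flank = config$motif_flank)
    pfm <- pfm_from_sequences(ctx)
    p3 <- reads[[primary]]
    pos3 <- read_end_position(p3$start, p3$end, p3$strand, "three_prime")
    tp_ctx <- three_prime_context(genome, p3$chrom, pos3, p3$strand,
                                  flank = config$motif_flank)
    motif <- list(tss_pfm = pfm, tss_ic = pfm_information_content(pfm),
                  three_prime = tp_ctx,
                  genome_gc = genome_gc_fraction(genome))
  } else {
    warning("no genome FASTA: motif stage skipped")
  }

  peaks <- if (!is.null(config$peaks)) load_peaks_bed(config$peaks) else
    call_strand_peaks(cov5[[primary]], min_count = config$peak_min_count,
                      min_separation = config$peak_min_separation)
  tss_all <- data.table(chrom = genes$chrom, pos = genes$tss)
  pass <- reann$table[status == "pass", .(chrom, pos = final_tss)]
  peaks_filt <- filter_promoter_proximal(peaks, rbind(tss_all, pass),
                                         exclusion = config$promoter_exclusion)
  regions <- merge_bidirectional(peaks_filt, max_gap = config$merge_gap)

  novel <- NULL
  if (!is.null(config$assembled_gtf)) {
    novel <- select_novel_transcripts(config$assembled_gtf, config$annotation)
  }

  summary <- pipeline_summary(genes, reann, anti, pausing, peaks_filt,
                              regions, novel)
  result <- structure(
    list(genes = genes, coverage = list(five_prime = cov5, three_prime = cov3),
         reannotation = reann, antisense = anti, correlation = correlation,
         pausing = pausing, three_prime = three_prime,
         length_by_pos = length_by_pos, initiation_classes = classes,
         motif = motif, peaks = peaks_filt, regions = regions, novel = novel,
         summary = summary, config = config),
    class = "startseq_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

# gene-aligned sense/divergent/convergent count matrix across replicates,
# and its Spearman correlation matrix
antisense_correlation_signals <- function(cov5, tss, anti, config) {
  cols <- list()
  for (r in names(cov5)) {
    cols[[paste0("sense_", r)]] <-
      window_counts_batch(cov5[[r]], tss, up = config$window,
                          down = config$window)
  }
  key <- paste(tss$gene_id, tss$occurrence)
  for (k in c("divergent", "convergent")) {
    ak <- anti[kind == k]
    idx <- match(paste(ak$gene_id, ak$occurrence), key)
    for (r in names(cov5)) {
      v <- rep(NA_integer_, nrow(tss))
      if (nrow(ak)) {
        anchors <- data.table(chrom = ak$chrom,
                              strand = fifelse(ak$gene_strand == "+", "-", "+"),
                              pos = ak$peak_position)
        v[idx] <- window_counts_batch(cov5[[r]], anchors,
                                      up = config$antisense_flank,
                                      down = config$antisense_flank)
      }
      cols[[paste0(k, "_", r)]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- key
  list(signals = m, matrix = antisense_correlation_matrix(m))
}

pipeline_summary <- function(genes, reann, anti, pausing, peaks, regions,
                             novel) {
  cc <- shift_class_counts(reann)
  s <- list(
    n_genes = nrow(genes),
    n_above_noise = unname(cc["pass"] + cc["fail_distance"]),
    n_pass = unname(cc["pass"]),
    shift_identical = unname(cc["identical"]),
    shift_within_5 = unname(cc["within_5"]),
    shift_within_10 = unname(cc["within_10"]),
    shift_gt_5 = unname(cc["gt_5"]),
    n_divergent = if (nrow(anti)) sum(anti$kind == "divergent") else 0L,
    n_convergent = if (nrow(anti)) sum(anti$kind == "convergent") else 0L,
    n_pi_genes = if (!is.null(pausing)) sum(!is.na(pausing$pausing_index))
                 else NA_integer_,
    n_peaks = nrow(peaks),
    n_bidirectional_regions = nrow(regions),
    n_novel_intergenic = if (!is.null(novel)) novel$n_intergenic else NA_integer_,
    n_novel_multi_exon = if (!is.null(novel)) novel$n_multi_exon else NA_integer_
  )
  s
}

#' @export
print.startseq_result <- function(x, ...) {
  s <- x$summary
  cat("<startseq_result>\n")
  for (k in names(s)) cat(sprintf("  %s: %s\n", k, s[[k]]))
  invisible(x)
}

write_pipeline_outputs <- function(result) {
  config <- result$config
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(result$reannotation$table, file.path(dir, "tss_reannotation.tsv"),
         sep = "\t")
  write_tss_bed(result$reannotation, file.path(dir, "tss_reannotated.bed"))
  fwrite(result$antisense, file.path(dir, "antisense_calls.tsv"), sep = "\t")
  fwrite(as.data.table(result$correlation$matrix, keep.rownames = "signal"),
         file.path(dir, "antisense_correlation.tsv"), sep = "\t")
  if (!is.null(result$pausing))
    fwrite(result$pausing, file.path(dir, "pausing_index.tsv"), sep = "\t")
  fwrite(data.table(offset = result$three_prime$offsets,
                    count = result$three_prime$profile),
         file.path(dir, "three_prime_profile.tsv"), sep = "\t")
  fwrite(result$length_by_pos, file.path(dir, "length_by_initiation.tsv"),
         sep = "\t")
  cls <- result$initiation_classes
  fwrite(data.table(
    class = c("upstream", "downstream"),
    n = c(cls$classes$upstream$n, cls$classes$downstream$n),
    centroid5 = c(cls$classes$upstream$centroid5,
                  cls$classes$downstream$centroid5),
    centroid3 = c(cls$classes$upstream$centroid3,
                  cls$classes$downstream$centroid3),
    peak3 = c(cls$classes$upstream$peak3, cls$classes$downstream$peak3),
    shift_statistic = cls$shift_statistic,
    centroid_gap = cls$centroid_gap
  ), file.path(dir, "initiation_classes.tsv"), sep = "\t")
  if (!is.null(result$motif)) {
    write_pfm_tsv(result$motif$tss_pfm, file.path(dir, "tss_inr_pfm.tsv"))
    if (!is.null(result$motif$three_prime$pfm))
      write_pfm_tsv(result$motif$three_prime$pfm,
                    file.path(dir, "three_prime_pfm.tsv"))
  }
  fwrite(result$peaks, file.path(dir, "peaks.tsv"), sep = "\t")
  write_elements_bed(result$peaks, file.path(dir, "peaks.bed"))
  fwrite(result$regions, file.path(dir, "bidirectional_regions.tsv"),
         sep = "\t")
  write_elements_bed(result$regions, file.path(dir, "bidirectional_regions.bed"))
  if (!is.null(result$novel))
    fwrite(result$novel$transcripts, file.path(dir, "novel_transcripts.tsv"),
           sep = "\t")
  for (r in names(result$coverage$five_prime)) {
    for (ek in c("five_prime", "three_prime")) {
      short <- if (ek == "five_prime") "fiveprime" else "threeprime"
      for (st in c("+", "-")) {
        stn <- if (st == "+") "plus" else "minus"
        write_bedgraph(result$coverage[[ek]][[r]], st,
                       file.path(dir, sprintf("%s.%s.%s.bedgraph",
                                              r, short, stn)))
      }
    }
  }
  fwrite(as.data.table(result$summary), file.path(dir, "summary.tsv"),
         sep = "\t")
  manifest <- list(
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("reads", "annotation", "genome",
                                           "fpkm", "blacklist", "peaks",
                                           "assembled_gtf", "out_dir"))],
    inputs = list(reads = as.list(config$reads), annotation = config$annotation,
                  genome = config$genome, fpkm = config$fpkm,
                  blacklist = config$blacklist, peaks = config$peaks,
                  assembled_gtf = config$assembled_gtf),
    primary_replicate = result$reannotation$primary,
    summary = result$summary
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
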