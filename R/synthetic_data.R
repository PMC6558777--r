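# Fully specified synthetic Start-seq experiment with ground truth: a random
# genome with an initiator-like motif written at every true TSS, a gene
# annotation carrying planted TSS misannotations, per-replicate stranded
# reads (sense initiation around the true TSS, divergent and convergent
# antisense initiation, intergenic bidirectional element pairs, uniform
# noise), and an expression table linked to the reads through a planted
# pausing index. Every emitted read is attributable to exactly one truth
# source via its name tag.

#' Default initiator-like position weight matrix
#'
#' A consensus-style pyrimidine/A initiator: Y Y A N W Y Y over offsets
#' -2..+4 with the initiating A at offset 0. Invented frequencies, intended
#' only as a recoverable planted motif.
#'
#' @return 4 x 7 probability matrix (rows A,C,G,T; columns offsets -2..4).
#' @export
default_inr_pwm <- function() {
  Y <- c(A = 0.05, C = 0.45, G = 0.05, T = 0.45)
  N <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  W <- c(A = 0.45, C = 0.05, G = 0.05, T = 0.45)
  A0 <- c(A = 0.85, C = 0.05, G = 0.05, T = 0.05)
  m <- cbind(Y, Y, A0, N, W, Y, Y)
  colnames(m) <- as.character(-2:4)
  m
}

#' Analytic per-offset information content of a PWM
#'
#' @param pwm Probability matrix (rows A,C,G,T).
#' @return Bits per offset (uniform background).
#' @export
pwm_information_content <- function(pwm) {
  apply(pwm, 2L, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
}

#' Configuration of the synthetic Start-seq experiment
#'
#' Defaults define the study conditions emulated throughout: 1000 genes with
#' annotation offsets ~ round(N(0, 20)) nt, two replicates of >= 50 sense
#' reads per gene around shared per-gene depths, 90% of 5' ends exactly at
#' the true TSS with geometric spillover, read lengths ~ N(35, 5) truncated
#' to [18, 47] nt, divergent initiation 80-200 nt upstream on 80% of genes,
#' convergent initiation 200-250 nt downstream on 60%, 30 intergenic
#' bidirectional elements at least 5 kb from any gene, 1% uniform noise
#' reads, and FPKM = sense reads / planted PI with 10% multiplicative noise.
#'
#' @param seed Mandatory RNG seed (integer).
#' @param n_genes,n_chrom,gc_content,body_len,min_gene_gap Genome layout.
#' @param chrom_length Chromosome length; `NULL` sizes it to fit the layout,
#'   a stated value too small to pack everything is an error.
#' @param annotated_offset_sd SD (nt) of the planted annotation error.
#' @param n_replicates Number of read replicates.
#' @param reads_per_gene List `meanlog`, `sdlog`, `min`: per-gene expected
#'   sense depth `lambda` ~ lognormal, replicate counts `min + Poisson(depth
#'   * lambda - min)`.
#' @param rep_depth Relative depth per replicate (replicate 1 deepest).
#' @param tss_purity Fraction of sense 5' ends exactly at the true TSS.
#' @param jitter_geom_p Geometric parameter of the off-TSS 5' spread
#'   (offset magnitude `1 + Geom(p)`, either side).
#' @param length_model List `mode` (`"distance_anchored"` or
#'   `"sequence_anchored"`), `mean`, `sd`, `min`, `max`, `upstream_bonus`
#'   (extra mean length for reads initiating upstream of the TSS),
#'   `pinned_offset3` (3'-end offset all sense reads share in
#'   sequence-anchored mode).
#' @param divergent,convergent Lists `fraction` (of genes carrying the
#'   signal), `offset_range` (nt from the sense TSS), `ratio` (antisense
#'   depth as a fraction of the gene's sense depth).
#' @param antisense_purity 5'-end purity at the planted antisense TSS.
#' @param n_elements,element_reads,element_purity,element_gap_range,element_spacing
#'   Intergenic bidirectional elements: count, per-strand reads
#'   (`base + Poisson(extra_mean)`), summit purity, intra-pair summit gap,
#'   and spacing between elements.
#' @param noise_rate Uniform noise reads as a fraction of signal reads.
#' @param pi_model List `meanlog`, `sdlog` of the planted pausing index and
#'   `fpkm_noise_sd` (multiplicative log-normal FPKM noise).
#' @param inr_pwm Probability matrix planted at every true TSS.
#' @return Config list of class `startseq_sim_config`.
#' @export
simulate_config <- function(seed,
                            n_genes = 1000L, n_chrom = 2L, gc_content = 0.42,
                            body_len = 1500L, min_gene_gap = 2500L,
                            chrom_length = NULL,
                            annotated_offset_sd = 20,
                            n_replicates = 2L,
                            reads_per_gene = list(meanlog = log(150),
                                                  sdlog = 0.5, min = 50L),
                            rep_depth = NULL,
                            tss_purity = 0.9,
                            jitter_geom_p = 0.15,
                            length_model = list(mode = "distance_anchored",
                                                mean = 35, sd = 5,
                                                min = 18L, max = 47L,
                                                upstream_bonus = 0,
                                                pinned_offset3 = 34L),
                            divergent = list(fraction = 0.8,
                                             offset_range = c(80L, 200L),
                                             ratio = 0.25),
                            convergent = list(fraction = 0.6,
                                              offset_range = c(200L, 250L),
                                              ratio = 0.12),
                            antisense_purity = 0.7,
                            n_elements = 30L,
                            element_reads = list(base = 30L, extra_mean = 10),
                            element_purity = 0.9,
                            element_gap_range = c(100L, 400L),
                            element_spacing = 6000L,
                            noise_rate = 0.01,
                            pi_model = list(meanlog = log(50), sdlog = 0.8,
                                            fpkm_noise_sd = 0.1),
                            inr_pwm = default_inr_pwm()) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  n_genes <- as.integer(n_genes); n_chrom <- as.integer(n_chrom)
  body_len <- as.integer(body_len); min_gene_gap <- as.integer(min_gene_gap)
  n_replicates <- as.integer(n_replicates)
  n_elements <- as.integer(n_elements)
  element_spacing <- as.integer(element_spacing)
  if (!is.null(chrom_length)) chrom_length <- as.integer(chrom_length)
  if (is.null(rep_depth)) rep_depth <- c(1, rep(0.7, n_replicates - 1L))
  stopifnot(length(rep_depth) == n_replicates,
            length_model$mode %in% c("distance_anchored", "sequence_anchored"),
            length_model$min < length_model$max,
            divergent$offset_range[1] <= divergent$offset_range[2],
            convergent$offset_range[1] <= convergent$offset_range[2])
  structure(as.list(environment()), class = "startseq_sim_config")
}

#' Generate the synthetic genome, gene annotation and truth records
#'
#' Lays genes (and, downstream of them, intergenic element pairs) on a random
#' genome at the stated GC content, writes an initiator-like PWM sample at
#' every true TSS (strand-aware), and plants the annotation error: the
#' annotated TSS is `true TSS + round(N(0, annotated_offset_sd))` in gene
#' orientation. Deterministic per seed.
#'
#' @param config [simulate_config()] result.
#' @return List: `genome` (`DNAStringSet`), `genes` (truth table with
#'   `true_tss`, `annotated_tss`, `annotated_offset`, body interval, per-gene
#'   depth and antisense truth), `elements` (paired summit truth), `config`.
#' @export
generate_genome_and_genes <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  spacing <- config$body_len + config$min_gene_gap
  per_chrom <- ceiling(n / config$n_chrom)
  chrom_names <- sprintf("chrS%d", seq_len(config$n_chrom))

  genes <- data.table(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom_names[((seq_len(n) - 1L) %/% per_chrom) + 1L],
    slot = ((seq_len(n) - 1L) %% per_chrom)
  )
  genes[, true_tss := 2000L + slot * spacing][, slot := NULL]
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, annotated_offset := as.integer(round(
    rnorm(.N, 0, config$annotated_offset_sd)))]
  genes[, annotated_tss := fifelse(strand == "+", true_tss + annotated_offset,
                                   true_tss - annotated_offset)]
  genes[, body_start := fifelse(strand == "+", annotated_tss,
                                annotated_tss - config$body_len + 1L)]
  genes[, body_end := body_start + config$body_len]
  genes[, lambda := pmax(config$reads_per_gene$min,
                         rlnorm(.N, config$reads_per_gene$meanlog,
                                config$reads_per_gene$sdlog))]
  genes[, divergent_present := runif(.N) < config$divergent$fraction]
  genes[, divergent_offset := fifelse(divergent_present, as.integer(
    sample(seq.int(config$divergent$offset_range[1],
                   config$divergent$offset_range[2]), .N, replace = TRUE)),
    NA_integer_)]
  genes[, convergent_present := runif(.N) < config$convergent$fraction]
  genes[, convergent_offset := fifelse(convergent_present, as.integer(
    sample(seq.int(config$convergent$offset_range[1],
                   config$convergent$offset_range[2]), .N, replace = TRUE)),
    NA_integer_)]

  # elements downstream of the genes on each chromosome, >= 5 kb from any gene
  per_chrom_el <- ceiling(config$n_elements / config$n_chrom)
  gene_end <- genes[, max(true_tss)] + config$body_len
  el_base <- gene_end + 5000L
  elements <- if (config$n_elements > 0L) {
    el <- data.table(
      element_id = sprintf("el%03d", seq_len(config$n_elements)),
      chrom = chrom_names[((seq_len(config$n_elements) - 1L) %/% per_chrom_el) + 1L],
      slot = ((seq_len(config$n_elements) - 1L) %% per_chrom_el)
    )
    el[, summit_plus := el_base + slot * config$element_spacing][, slot := NULL]
    el[, summit_minus := summit_plus + as.integer(
      sample(seq.int(config$element_gap_range[1], config$element_gap_range[2]),
             .N, replace = TRUE))]
    el
  } else {
    data.table(element_id = character(), chrom = character(),
               summit_plus = integer(), summit_minus = integer())
  }

  needed <- max(gene_end,
                if (nrow(elements)) max(elements$summit_minus) else 0L) + 2000L
  chrom_len <- if (is.null(config$chrom_length)) needed else config$chrom_length
  if (chrom_len < needed)
    stop("chrom_length ", chrom_len, " too small; layout needs ", needed)

  base_prob <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                 G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  genome <- lapply(chrom_names, function(ch) {
    bases <- sample(names(base_prob), chrom_len, replace = TRUE,
                    prob = base_prob)
    gch <- genes[chrom == ch]
    if (nrow(gch)) {
      motif_off <- as.integer(colnames(config$inr_pwm))
      motifs <- sample_pwm(config$inr_pwm, nrow(gch))
      for (k in seq_len(nrow(gch))) {
        m <- motifs[k, ]
        if (gch$strand[k] == "+") {
          bases[gch$true_tss[k] + motif_off + 1L] <- m
        } else {
          bases[gch$true_tss[k] - motif_off + 1L] <- complement_bases(m)
        }
      }
    }
    paste(bases, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(genome), chrom_names))
  list(genome = genome, genes = genes[], elements = elements[],
       config = config)
}

sample_pwm <- function(pwm, n) {
  m <- matrix("", nrow = n, ncol = ncol(pwm))
  for (j in seq_len(ncol(pwm))) {
    m[, j] <- sample(rownames(pwm), n, replace = TRUE, prob = pwm[, j])
  }
  m
}

complement_bases <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

# truncated-normal integer lengths by rejection
rtrunc_length <- function(n, mean, sd, lo, hi) {
  out <- integer(n)
  todo <- seq_len(n)
  mean <- rep_len(mean, n)
  while (length(todo)) {
    draw <- as.integer(round(rnorm(length(todo), mean[todo], sd)))
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# geometric two-sided jitter: 0 with prob purity, else +/- (1 + Geom(p))
jitter_offsets <- function(n, purity, p, cap = 450L) {
  off <- integer(n)
  j <- runif(n) >= purity
  nj <- sum(j)
  if (nj) {
    mag <- pmin(1L + rgeom(nj, p), cap)
    off[j] <- mag * sample(c(-1L, 1L), nj, replace = TRUE)
  }
  off
}

#' Simulate Start-seq reads for every replicate
#'
#' Emits sense reads per gene (5' ends at the true TSS with probability
#' `tss_purity`, otherwise geometric spillover; lengths per the configured
#' length model), divergent/convergent antisense reads at the planted
#' offsets, opposite-strand read pairs at element summits, and uniform noise.
#' Read names tag the truth source (`<gene>|sense`, `<gene>|divergent`,
#' `<gene>|convergent`, `<element>|plus|minus`, `noise`). Minus-strand genes
#' are fully mirrored.
#'
#' @param sim A [generate_genome_and_genes()] result.
#' @return `sim` extended with `reads` (named list of per-replicate read
#'   tables) and per-replicate truth counts (`n_sense_repK`,
#'   `n_divergent_repK`, `n_convergent_repK` on `genes`; `n_plus_repK`,
#'   `n_minus_repK` on `elements`).
#' @export
simulate_startseq <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1L)
  genes <- sim$genes
  lm <- config$length_model
  chrom_len <- Biostrings::width(sim$genome)[1L]
  reads <- vector("list", config$n_replicates)
  names(reads) <- paste0("rep", seq_len(config$n_replicates))

  for (r in seq_len(config$n_replicates)) {
    depth <- config$rep_depth[r]
    n_sense <- config$reads_per_gene$min +
      rpois(nrow(genes), pmax(genes$lambda * depth - config$reads_per_gene$min, 0))
    gi <- rep(seq_len(nrow(genes)), n_sense)
    off <- jitter_offsets(length(gi), config$tss_purity, config$jitter_geom_p)
    if (lm$mode == "sequence_anchored") {
      # redraw offsets whose implied length (pinned 3' end) leaves [min, max]
      lo_off <- lm$pinned_offset3 + 1L - lm$max
      hi_off <- lm$pinned_offset3 + 1L - lm$min
      bad <- which(off < lo_off | off > hi_off)
      while (length(bad)) {
        off[bad] <- jitter_offsets(length(bad), config$tss_purity,
                                   config$jitter_geom_p)
        bad <- bad[off[bad] < lo_off | off[bad] > hi_off]
      }
      len <- lm$pinned_offset3 + 1L - off
    } else {
      len <- rtrunc_length(length(gi),
                           lm$mean + lm$upstream_bonus * (off < 0L),
                           lm$sd, lm$min, lm$max)
    }
    strand <- genes$strand[gi]
    pos5 <- fifelse(strand == "+", genes$true_tss[gi] + off,
                    genes$true_tss[gi] - off)
    sense <- data.table(
      chrom = genes$chrom[gi],
      start = fifelse(strand == "+", pos5, pos5 - len + 1L),
      end = fifelse(strand == "+", pos5 + len, pos5 + 1L),
      strand = strand,
      name = paste0(genes$gene_id[gi], "|sense")
    )

    anti <- rbindlist(lapply(c("divergent", "convergent"), function(kind) {
      cfg <- config[[kind]]
      present <- genes[[paste0(kind, "_present")]]
      idx <- which(present)
      if (!length(idx)) return(NULL)
      n_anti <- rpois(length(idx), cfg$ratio * genes$lambda[idx] * depth)
      ai <- rep(idx, n_anti)
      if (!length(ai)) return(NULL)
      d <- genes[[paste0(kind, "_offset")]][ai]
      sgn <- if (kind == "divergent") -1L else 1L
      aoff <- sgn * d + jitter_offsets(length(ai), config$antisense_purity,
                                       config$jitter_geom_p, cap = 40L)
      gstrand <- genes$strand[ai]
      astrand <- fifelse(gstrand == "+", "-", "+")
      apos5 <- fifelse(gstrand == "+", genes$true_tss[ai] + aoff,
                       genes$true_tss[ai] - aoff)
      alen <- rtrunc_length(length(ai), lm$mean, lm$sd, lm$min, lm$max)
      data.table(
        chrom = genes$chrom[ai],
        start = fifelse(astrand == "+", apos5, apos5 - alen + 1L),
        end = fifelse(astrand == "+", apos5 + alen, apos5 + 1L),
        strand = astrand,
        name = paste0(genes$gene_id[ai], "|", kind)
      )
    }))

    el <- sim$elements
    elem <- if (nrow(el)) {
      rbindlist(lapply(c("plus", "minus"), function(side) {
        n_el <- config$element_reads$base +
          rpois(nrow(el), config$element_reads$extra_mean)
        ei <- rep(seq_len(nrow(el)), n_el)
        eoff <- jitter_offsets(length(ei), config$element_purity,
                               config$jitter_geom_p, cap = 40L)
        summit <- if (side == "plus") el$summit_plus[ei] else el$summit_minus[ei]
        estrand <- if (side == "plus") "+" else "-"
        epos5 <- if (side == "plus") summit + eoff else summit - eoff
        elen <- rtrunc_length(length(ei), lm$mean, lm$sd, lm$min, lm$max)
        data.table(
          chrom = el$chrom[ei],
          start = if (side == "plus") epos5 else epos5 - elen + 1L,
          end = if (side == "plus") epos5 + elen else epos5 + 1L,
          strand = estrand,
          name = paste0(el$element_id[ei], "|", side)
        )
      }))
    } else NULL

    n_signal <- nrow(sense) + (if (is.null(anti)) 0L else nrow(anti)) +
      (if (is.null(elem)) 0L else nrow(elem))
    n_noise <- as.integer(round(config$noise_rate * n_signal))
    noise <- if (n_noise > 0L) {
      npos5 <- as.integer(runif(n_noise, 500, chrom_len - 500))
      nstrand <- sample(c("+", "-"), n_noise, replace = TRUE)
      nlen <- rtrunc_length(n_noise, lm$mean, lm$sd, lm$min, lm$max)
      data.table(
        chrom = sample(names(sim$genome), n_noise, replace = TRUE),
        start = fifelse(nstrand == "+", npos5, npos5 - nlen + 1L),
        end = fifelse(nstrand == "+", npos5 + nlen, npos5 + 1L),
        strand = nstrand,
        name = "noise"
      )
    } else NULL

    reads[[r]] <- rbindlist(list(sense, anti, elem, noise))
  }

  # truth bookkeeping from the emitted reads themselves
  for (r in names(reads)) {
    tags <- tstrsplit(reads[[r]]$name, "|", fixed = TRUE)
    src <- data.table(id = tags[[1]],
                      what = if (length(tags) > 1L) tags[[2]] else NA_character_)
    tally <- src[!is.na(what), .N, by = .(id, what)]
    for (w in c("sense", "divergent", "convergent")) {
      cnt <- tally[what == w][data.table(id = genes$gene_id), on = "id"]
      set(genes, j = paste0("n_", w, "_", r),
          value = fifelse(is.na(cnt$N), 0L, cnt$N))
    }
    if (nrow(sim$elements)) {
      for (w in c("plus", "minus")) {
        cnt <- tally[what == w][data.table(id = sim$elements$element_id),
                                on = "id"]
        set(sim$elements, j = paste0("n_", w, "_", r),
            value = fifelse(is.na(cnt$N), 0L, cnt$N))
      }
    }
  }
  sim$genes <- genes[]
  sim$reads <- reads
  sim
}

#' Simulate the expression table linked through a planted pausing index
#'
#' Plants a per-gene pausing index ~ lognormal and inverts the PI definition:
#' `fpkm = n_sense_rep1 / planted_PI`, perturbed by multiplicative log-normal
#' noise. Also emits an independent small counts-plus-lengths table for
#' validating [compute_fpkm()].
#'
#' @param sim A [simulate_startseq()] result.
#' @return `sim` extended with `fpkm` (`gene_id`, `fpkm`), `planted_pi` on
#'   `genes`, and `rna_counts` (`gene_id`, `count`, `length`,
#'   `library_total`).
#' @export
simulate_expression <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 2L)
  genes <- sim$genes
  genes[, planted_pi := rlnorm(.N, config$pi_model$meanlog,
                               config$pi_model$sdlog)]
  noise <- exp(rnorm(nrow(genes), 0, config$pi_model$fpkm_noise_sd))
  fpkm <- data.table(gene_id = genes$gene_id,
                     fpkm = genes$n_sense_rep1 / genes$planted_pi * noise)
  library_total <- 2e7
  rna_counts <- data.table(
    gene_id = genes$gene_id,
    count = as.integer(round(fpkm$fpkm * config$body_len * library_total / 1e9)),
    length = config$body_len,
    library_total = library_total
  )
  sim$genes <- genes[]
  sim$fpkm <- fpkm
  sim$rna_counts <- rna_counts
  sim
}

#' Run the full synthetic experiment
#'
#' [generate_genome_and_genes()], [simulate_startseq()] and
#' [simulate_expression()] in sequence. Fully deterministic per
#' `config$seed`.
#'
#' @param config A [simulate_config()] result.
#' @return Simulation bundle with genome, annotation truth, reads, expression.
#' @export
simulate_startseq_experiment <- function(config) {
  simulate_expression(simulate_startseq(generate_genome_and_genes(config)))
}

#' Annotation table (as a pipeline input) of a simulation
#'
#' The annotated (planted-error) gene records in the same shape as
#' [load_gene_annotation()] output.
#'
#' @param sim Simulation bundle.
#' @return Gene `data.table` keyed on the annotated TSS.
#' @export
sim_annotation <- function(sim) {
  g <- sim$genes[, .(gene_id, occurrence = 1L, chrom, strand,
                     tss = annotated_tss, body_start, body_end)]
  setorder(g, chrom, tss)
  g[]
}

#' Write a simulation bundle to disk
#'
#' Emits the genome FASTA, the annotation GTF (annotated, planted-error
#' coordinates), per-replicate BED6 reads, FPKM and counts TSVs, truth tables
#' and a YAML manifest echoing the full configuration and all paths.
#'
#' @param sim Simulation bundle.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (also stored in the manifest).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "genes.gtf"),
                fpkm = file.path(dir, "fpkm.tsv"),
                rna_counts = file.path(dir, "rna_counts.tsv"),
                truth_genes = file.path(dir, "truth_genes.tsv"),
                truth_elements = file.path(dir, "truth_elements.tsv"),
                manifest = file.path(dir, "manifest.yaml"))
  write_genome_fasta(sim$genome, paths$genome)
  ann <- sim_annotation(sim)
  gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$body_start + 1L, ann$body_end),
    strand = ann$strand)
  gr$type <- "gene"; gr$gene_id <- ann$gene_id; gr$source <- "startseq_sim"
  rtracklayer::export(gr, paths$annotation, format = "gtf")
  for (r in names(sim$reads)) {
    paths[[paste0("reads_", r)]] <- file.path(dir, paste0("reads_", r, ".bed"))
    write_reads(sim$reads[[r]], paths[[paste0("reads_", r)]])
  }
  fwrite(sim$fpkm, paths$fpkm, sep = "\t")
  fwrite(sim$rna_counts, paths$rna_counts, sep = "\t")
  fwrite(sim$genes, paths$truth_genes, sep = "\t")
  fwrite(sim$elements, paths$truth_elements, sep = "\t")
  manifest <- list(config = config_for_manifest(sim$config),
                   paths = lapply(paths, normalizePath, mustWork = FALSE))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$inr_pwm <- apply(config$inr_pwm, 2L, as.numeric, simplify = FALSE)
  cfg
}
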