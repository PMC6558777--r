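---
title: "Methods: TSS refinement, antisense calling and Pol II pausing from Start-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS refinement, antisense calling and Pol II pausing from Start-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startseq)
library(data.table)
```

## The data and the model

Start-seq sequences short 5'-capped RNAs held by promoter-proximally paused
RNA polymerase II. Each read carries two signals: its 5' end marks the single
nucleotide at which Pol II initiated transcription, and its 3' end marks the
position at which Pol II paused. The package takes aligned reads as stranded
BED6 intervals and reduces them to two sparse, strand-specific
single-nucleotide coverage maps — one of 5' ends, one of 3' ends — from which
every downstream analysis is computed.

All coordinates are internally 0-based and half-open, matching BED; GTF input
(1-based, closed) is converted on load. A TSS is the 0-based position of the
initiating base: the interval start on the plus strand, the interval end
minus one on the minus strand. All windows are anchor-oriented: offset +10
means 10 nt downstream *in gene orientation*, i.e. toward decreasing genomic
coordinates for a minus-strand gene. Window boundaries are inclusive on both
sides, so a "±500 bp" window covers 1001 positions; whether boundary
positions are included is immaterial at these window sizes but is fixed here
as a package-wide convention.

## TSS reannotation

For each annotated gene TSS, the sense-strand position with the most read 5'
ends within ±500 bp is the candidate reannotated TSS. Ties are broken toward
the smallest absolute offset, then upstream; ties are rare at realistic
depth, but the rule makes the caller deterministic. Two filters follow, in
this order:

1. **Noise filter.** A gene is discarded if its sense window count is below
   10 reads in *any* replicate. The threshold is a per-replicate conjunction:
   one underpowered replicate disqualifies the gene.
2. **Distance filter.** The signed peak offsets of all noise-passing genes
   are fitted to a normal distribution per replicate (plain sample mean and
   SD, no trimming). A replicate call passes iff |offset − mean| ≤ SD,
   boundary inclusive; the gene passes iff every replicate passes. The 1-SD
   band around the fitted mean is read as the maximum distance at which a
   peak can still be attributed to the annotated gene rather than a
   neighbouring start site. One SD (rather than a symmetric fixed window) is
   used because the spread of annotation error is a property of the
   annotation being corrected, not of the assay.

Passing genes take their final TSS from the *primary* replicate — by default
the replicate with the largest genome-wide read total, following the
convention that the deepest library defines positions and the others confirm
them. A pooled mode is deliberately not the default: independent replicate
calls give the distance filter its replicate-agreement meaning.

Shift classes are reported as exclusive bins on |final − annotated|
(identical, 1–5, 6–10, >10 nt), with `shift_class_counts()` additionally
reporting the cumulative tallies (identical, ≤5, ≤10, >5 nt) that are the
usual headline numbers for this kind of reannotation.

Genes sharing an id but annotated with distinct TSSs are retained as separate
analysis units keyed on `(gene_id, occurrence)`; collapsing them would
silently merge distinct promoters.

## Antisense calling

Divergent and convergent TSSs are called on the strand opposite the gene,
scanning gene-oriented offsets [−500, −1] (divergent, upstream, pointing away
from the gene) and [+1, +500] (convergent, downstream, pointing back at the
promoter) from the final sense TSS. Offset 0 belongs to neither window, which
keeps the two searches disjoint. The same 10-count noise threshold is
applied, interpreted as the opposite-strand *window total* — symmetric with
the sense noise filter; a peak-height threshold would conflate sharpness with
presence. Correlation analyses use the ±50 nt antisense-strand count around
each called peak, and Spearman correlations are computed pairwise-complete
over the gene universe, with cells having fewer than 3 complete pairs
reported missing.

## Pausing quantification

The pausing index of a gene is its sense TSS ±500 bp 5'-end count divided by
the gene's FPKM; genes with zero or missing FPKM are reported missing rather
than infinite, since an undefined denominator is an expression-measurement
failure, not evidence of extreme pausing. FPKM from raw counts is
`count × 10^9 / (library_total × length)`.

Pause positions are read from 3'-end metaprofiles over ±150 nt around final
TSSs. For RNA-length analyses, reads are assigned to a gene when they lie on
its strand with their 5' end within ±150 nt of its final TSS, regardless of
exact initiation position; each read goes to at most one gene (nearest TSS,
ties to the upstream gene). Reads longer than 47 nt are excluded from
length statistics: 47 nt is the longest insert identifiable by adapter
trimming at a 50-nt read length, so longer RNAs are censored, not absent.

**Initiation-anchored analysis.** To separate distance-anchored from
sequence-anchored pausing, reads are classified by their 5' offset into an
upstream band [−10, −5] and a downstream band [+5, +40]; the band between
them is excluded so neither class is contaminated by the dominant exact-TSS
initiation. The headline shift statistic is the difference of the class
3'-offset *centroids* (means), downstream minus upstream. Under pausing
anchored to the initiation site, each read's 3' end is its 5' end plus an
independent length, so the 3'-centroid difference equals the 5'-centroid gap
exactly in expectation; under pausing pinned to the DNA sequence the class 3'
distributions coincide and the statistic is 0. Centroids are used rather
than profile modes because the class 5' distributions are one-sided and
skewed: the mode of a convolved profile does not track the 5' mean, whereas
the mean does, exactly. Per-class 3' profile peak offsets are still reported
for inspection. Classes with fewer than 100 reads (configurable) are flagged
underpowered and yield no statistic.

## Motif context

Sequence contexts are extracted strand-aware around anchor positions, with
minus-strand anchors reverse-complemented so the center base is always the
template-directed initiating (or pausing) base. Information content per
offset is `2 + Σ f log2 f` bits against a uniform background, with no
pseudocounts and no small-sample correction; the plug-in estimator's upward
bias is ~`3/(2 ln2 · n)` bits and the tests account for it explicitly.
Ambiguous bases are excluded per offset rather than per sequence, so a
single N does not discard an otherwise informative context.

## Non-genic elements

The peak caller is a deliberately simple greedy summit selector: positions
with ≥10 read 5' ends are visited in descending count order (ascending
position at ties, for determinism) and accepted if ≥150 nt from every
previously accepted same-strand summit. It stands in for factor-style peak
callers whose exact behaviour is parameter-dependent; an externally called
peak BED is accepted in its place so the downstream filter and merge stages
can be reproduced bit-for-bit against any upstream caller. Peaks within
±3 kb (summit-based, inclusive) of any known or assembled TSS are removed;
remaining peaks are chained when consecutive summits are ≤3000 bp apart, and
a maximal chain of ≥2 peaks containing at least one *adjacent*
opposite-strand pair becomes a bidirectional region — the two-strand
initiation signature of active enhancers. "Adjacent" is read as
consecutive-in-coordinate-order, giving chains rather than all-pairs
cliques. Candidate novel genes from an assembly GTF are transcripts none of
whose exons overlaps a known gene body by any base, retained only when
multi-exonic, because short-read assemblers over-report single-exon
transcripts.

## The synthetic experiment

The generator builds a complete toy study whose every quantity is planted
and recorded, so each pipeline stage can be tested against truth without
external data. Its defaults are the study conditions used throughout the
tests and the acceptance script:

| parameter | default | what it emulates |
|---|---|---|
| genes | 1000 on 2 chromosomes | the reannotatable gene set |
| annotation offset | round(N(0, 20)) nt | planted TSS misannotation |
| sense reads/gene | ≥50, two replicates, Poisson around a shared lognormal depth (median ~150, replicate 2 at 0.7×) | per-promoter Start-seq coverage with a deeper primary replicate and planted replicate correlation |
| TSS purity | 0.9, geometric (p = 0.15) two-sided spillover | focused initiation with minor off-TSS starts populating the ±10/+40 bands |
| read length | round(truncN(35, 5)) on [18, 47] | pause distance ~35 nt; adapter-trimming censoring at 47 |
| divergent | 80% of genes, U[80, 200] nt upstream, ~25% of sense depth | upstream antisense initiation |
| convergent | 60% of genes, U[200, 250] nt downstream, ~12% of sense depth | weaker, more distal convergent initiation |
| elements | 30 opposite-strand summit pairs (gap U[100, 400]), ≥5 kb from genes | intergenic bidirectional (enhancer-like) loci |
| noise | 1% of signal reads, uniform | unattributable background |
| genome | GC 0.42 | mammalian-like base composition |
| expression | FPKM = sense reads / planted PI, ×lognormal(0, 0.1) | PI definition inverted so pausing has a recoverable truth |
| Inr motif | YYANWYY-style PWM, A at offset 0 | initiator context written at every true TSS |

Two length-model modes give the anchored-pausing analysis its ground truths:
`distance_anchored` draws each read's length independently of its start
(optionally +2.5 nt for upstream-initiating reads, the planted analogue of
upstream RNAs running 2–3 nt longer), while `sequence_anchored` pins every
sense 3' end of a gene to one genomic position, redrawing starts whose
implied length leaves [18, 47]. The upstream bonus defaults to 0 and is
switched on only where that effect is itself under study, so the
distance-anchored shift statistic has a clean expectation.

All randomness flows through R's default RNG from the mandatory seed (stage
seeds are `seed`, `seed+1`, `seed+2`), and every emitted read is attributable
to exactly one truth source via its name tag, which the tests tally against
the truth tables exactly.

What the generator does *not* emulate — mappability artifacts, rRNA
contamination, sequence-dependent ligation bias, overlapping genes, CpG
island structure, chromatin-positioned antisense offsets — bounds what
passing tests show: they demonstrate that the estimators recover what the
data contain, not that real libraries contain only these structures.

## Numerical and degenerate-input choices

* Peak ties: smallest |offset|, then upstream; antisense ties: nearest the
  sense TSS. Logged per call via the deterministic ordering.
* An offset fit needs ≥2 offsets and nonzero SD; a zero-SD fit is an error
  (degenerate annotation), not silently passed through.
* `spearman_rho` uses average ranks for ties and returns missing on zero
  variance or <3 complete pairs.
* Empty windows yield a no-peak call that fails the noise filter downstream;
  unknown chromosomes count 0 with a warning.
* Problem sizes in the tests (60–1000 genes, 2 chromosomes of ~2 Mb) were
  chosen so the full suite exercises every stage at depths where the planted
  effects are statistically unambiguous.

## Known limitations

* The pausing index inherits FPKM's compositional and length biases; it is a
  ratio, not a rate.
* The greedy peak caller has no local background model; on real data an
  external caller is recommended via `peaks =`.
* The 10-count antisense threshold under-reports convergent transcription at
  moderate depth (by design, matching the sense filter); the package reports
  call fractions, not a corrected prevalence.
* Multi-TSS gene ids are analysed per occurrence; downstream consumers that
  need one row per gene id must choose a representative themselves.
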