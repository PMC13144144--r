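---
title: "Peak co-localization and degenerate motif enrichment: methods"
author: "MotifColoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak co-localization and degenerate motif enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifColoc)
library(GenomicRanges)
```

## Scope and model

MotifColoc answers two questions about a pair of ChIP-seq peak sets A
and B on the same genome — in the motivating application, ORC ChIP-seq
peaks and RPA ChIP-ssSeq peaks in *Saccharomyces cerevisiae*, where RPA
enrichment marks ssDNA-forming loci:

1. which loci are co-occupied by both factors, and
2. whether the co-occupied loci share a sequence motif beyond what their
   nucleotide composition explains.

The package consumes *called peaks* (BED-like intervals, e.g. SICER2
output) and *normalized coverage tracks* (bedGraph, e.g. RPGC-normalized
signal in 1-bp bins). Read processing, alignment, normalization and peak
calling are upstream and out of scope; tracks and peaks are taken as
given. Position-weight-matrix motif discovery is likewise external: this
package tests *given* consensus patterns at the sequence level.

### Co-localization

Each peak is reduced to its **summit**, the leftmost position of maximum
coverage within the peak; summits are then expanded to symmetric windows
of half-width $w$ (length $2w+1$, the summit exactly central, clipped at
chromosome boundaries). The union of the two window sets is partitioned
into the connected components of its interval-overlap graph.
Co-localization means **at least one shared base**: under half-open
interval arithmetic, windows that merely touch are disjoint. Components
containing windows from both sets are *shared clusters*; each is counted
once in the Venn tally, preventing redundant counting of partially
overlapping signals, and is represented downstream by a fresh
$\pm w$ window centered on the cluster midpoint. Components from a
single set count as A-only / B-only, per window by default (see
*Open design choices*).

### Degenerate matching and enrichment

A pattern is a string over $\{A, C, G, T, N\}$. $N$ positions match any
base and are excluded from mismatch counting; only the fixed positions
define the matching criteria, so an exact 10-mer and an 18-bp pattern
with 10 fixed positions are handled identically. A window is
**motif-positive** if at least one offset (and, per the strand mode, one
strand) aligns the pattern with at most $m$ fixed-position mismatches.
Windows shorter than the pattern are negative, not errors.

Motif-positive counts in the target set (shared-cluster windows) versus
the background set (A-only plus B-only windows, controlling for
assay-specific biases from either side) form a 2×2 table, assessed with
the two-sided Fisher exact test and summarised by the cross-product odds
ratio $(ad)/(bc)$ ($\infty$ when $bc = 0$ and $ad > 0$; an optional
Haldane–Anscombe correction adds 0.5 to each cell). Raw p-values are
reported; no multiple-testing adjustment is applied at this stage.

### Permutation control for composition

Enrichment of a GC-rich pattern could in principle reflect GC bias of
the target windows. The permutation test therefore re-shuffles every
target with an **exact dinucleotide-preserving shuffle** and recomputes
the positive count under the same criteria. The shuffle is the
Altschul–Erickson construction: a uniform random Eulerian trail on the
sequence's dinucleotide multigraph, sampled by drawing per-vertex last
edges until they form a tree into the terminal vertex. It conserves the
dinucleotide multiset, both terminal characters and the length of every
sequence *exactly* — an assertable invariant, which is why swap-based
approximate shufflers were rejected. $N$ characters participate as an
ordinary fifth letter, so their counts and adjacencies are preserved
too. The empirical p-value is

$$p = \frac{r + 1}{n + 1},$$

with $r$ the number of permuted datasets whose positive count is greater
than or equal to the observed count (ties count toward $r$) and $n$ the
number of permutations. This estimator can never be 0 and attains its
floor $1/(n+1)$ — with the conventional $n = 10{,}000$, just under
$10^{-4}$. Only the targets are shuffled; the permutation statistic is
the target positive count, not an odds ratio against the (untouched)
background.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window half-width $w$ | 150 | bases | summit-centered $\pm$150-bp windows are the conventional scale for compact-genome ChIP peaks; any value in 0–500 is supported and shared counts are monotone in $w$ |
| mismatch allowance $m$ | 0 | fixed positions | exact matching as the headline; 1–2 mismatches probe degenerate occurrences (detection can only grow with $m$) |
| strand mode | forward | — | headline counts are forward-strand; reverse-complement enrichment is reported separately via `"revcomp"`/`"both"` |
| permutations $n$ | 10,000 | — | p-value floor just under $10^{-4}$; smaller $n$ (199–999) is adequate for calibration studies |
| scaled-matrix bins | user-set | bins | region-scaled heatmaps have no canonical bin count; it is an explicit parameter |
| summit flank | 1000 | bases | $\pm$1-kb metaprofiles at 1-bp bins |

## Numerical conventions

- **Coordinates.** Files are BED-native (0-based, half-open); in memory
  everything is 1-based closed `GRanges`/`IRanges`, the Bioconductor
  convention. Conversions happen only at I/O boundaries.
- **Summit ties** break leftmost; an all-zero peak falls back to the
  interval midpoint. Both rules are arbitrary but deterministic.
- **Cluster midpoints** use the floor of the mean of the 0-based bounds;
  on even-length clusters this biases half a base leftward, immaterial
  at $w = 150$ but fixed for reproducibility.
- **Windows crossing chromosome ends** are clipped, not dropped; coverage
  queries beyond a track's extent (or on chromosomes absent from it)
  return 0.
- **Two-sided Fisher p** is the sum of hypergeometric point
  probabilities not exceeding the observed probability times
  $1 + 10^{-7}$; the tolerance absorbs floating-point ties. The
  implementation is pinned in tests by a full-enumeration oracle over
  every table with margins ≤ 30 (worst deviation around $10^{-14}$) and
  cross-checked against `stats::fisher.test()`.
- **Sequence N at a fixed position counts as a mismatch** — assembly
  gaps can never create matches. FASTA input is uppercased and every
  non-ACGT character becomes N, so soft-masking is ignored.
- **Only N is a degenerate code.** Full IUPAC support would be a
  documented extension; the matching semantics here are deliberately
  minimal.
- **Scaled bins** split a region into contiguous ranges as equal as
  possible, remainder spread left-first; regions shorter than the bin
  count reuse single bases so no bin is empty. Row sorting by mean is
  stable and can take an external key matrix (sort one factor's heatmap
  by another factor's signal over the same regions).
- **Determinism.** All randomness flows through R's RNG (the C++ layers
  draw from it too), so a seed fixes every result; `runFullAnalysis()`
  reports carry no timestamps and are byte-identical across reruns.

## The synthetic-data generator

`genGenome()` draws i.i.d. bases at a given GC fraction (default 0.38,
the budding-yeast genome average). `genPeaksCoverage()` plants shared
peak pairs whose summits differ by at most $d$ (default 100 bases) plus
isolated single-set peaks separated by at least `minGap` (default
2000 bases), with triangular coverage giving each peak a strict unique
maximum at its planted summit. The defaults satisfy the guarantees
$d \le 2w$ (planted pairs must overlap after $\pm w$ expansion) and
$\mathrm{minGap} > 2w + 1$ (planted singles must stay isolated), so
classification recovers the planted labels exactly — which is a test of
the classifier, not of the generator. `plantMotifSequences()` designates
each window positive with prevalence $\pi_t$ (targets) or $\pi_b$
(background), plants one instance at a uniform offset with a drawn
mismatch count, and rejection-samples designated negatives until they
contain no qualifying match; designation-then-rejection yields exact
ground-truth flags at the cost of slight composition distortion in the
negatives, acceptable because the enrichment test compares counts, and
the permutation module has its own composition-exact control
(`shuffleBackground()`).

What the generator does **not** emulate: read-level noise, fragment-size
effects, mappability, copy-number and repeat structure, chromatin
context, correlated peak shapes, or the actual origin/ssDNA biology of
a real genome. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not performance on real data.

## Validation problem sizes

The test suite validates, among others: scanning against an exhaustive
offset-by-offset oracle; clustering against brute-force all-pairs
connected components on 200 random instances of up to 500 windows;
exact dinucleotide/endpoint conservation over 1000 random 301-nt
shuffles; null calibration of the permutation p-value over 500
replicates at $n = 199$ (empirical rejection at the 5% level stays
within simulation error of nominal); and recovery of a design odds
ratio of 19 ($\pi_t = 0.5$, $\pi_b = 0.05$, 500 windows per set) within
two-fold in at least 95 of 100 seeds. These sizes were chosen as the
smallest that make the statistical assertions sharp.

## A compact end-to-end run

```{r example, eval = FALSE}
genome <- genGenome(c(chrI = 300000L, chrII = 200000L), seed = 42)
synth  <- genPeaksCoverage(genome, nShared = 8, nAOnly = 5, nBOnly = 4,
                           seed = 42)
pat <- "GGTTCGAACC"   # GC-rich near-palindromic core, its own revcomp
for (i in which(synth$truth$label == "shared")) {
  ch <- synth$truth$chrom[i]; at <- synth$truth$summitA[i] - 4L
  s <- as.character(genome[[ch]]); substr(s, at, at + 9L) <- pat
  genome[[ch]] <- Biostrings::DNAString(s)
}

sl <- seqLengths(genome)
pa <- peakSummits(granges(synth$peaksA), synth$trackA)
pb <- peakSummits(granges(synth$peaksB), synth$trackB)
wa <- expandWindows(as.character(seqnames(pa)), mcols(pa)$summit, 150, sl)
wb <- expandWindows(as.character(seqnames(pb)), mcols(pb)$summit, 150, sl)
coloc <- classifyOverlap(wa, wb)
vennCounts(coloc)

cl <- clusters(coloc)
targets <- extractWindowSeqs(genome,
  clusterWindows(cl[mcols(cl)$label == "shared"], 150, sl))
spec <- matchSpec(pat, maxMismatch = 1L)
permutationTest(targets, spec, nPerm = 999, seed = 1)
```

`runFullAnalysis()` wraps the same stages behind a YAML configuration
and writes BED/FASTA/TSV intermediates plus a JSON report whose
contingency margins equal the emitted window counts by construction.

## Known limitations

- Backgrounds built from A-only/B-only windows inherit whatever biases
  make those loci single-set; the composition-matched shuffle control is
  the complementary check, and both should be read together.
- The exact window width used for sequence scoring matters (positivity
  is monotone in window length); it is therefore always an explicit
  parameter, never an implicit default of the scoring stage.
- The cross-product odds ratio is unstable at small counts (infinite
  with a zero cell); the Haldane-corrected variant is available but
  changes the estimand slightly.
- Clustering treats windows as unweighted intervals; no account is taken
  of signal strength when merging, so a weak window can bridge two
  strong clusters into one.
- With `"both"` strands, a single double-counted palindromic instance
  still yields one positive window — scoring is binary by design, and
  occurrence counts per window are deliberately not a statistic here.
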