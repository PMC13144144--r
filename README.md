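# MotifColoc

Genome-wide co-localization of two ChIP-seq peak sets and sequence-level
motif enrichment at their shared loci, for the setting where one factor
marks ssDNA-forming regions (e.g. RPA ChIP-ssSeq) and the other is a
DNA-binding complex of interest (e.g. ORC ChIP-seq) in budding yeast or
any compact genome. The package is aimed at analysts who already have
peak calls and normalized coverage tracks and want a reproducible,
statistically explicit answer to two questions:

1. **Where do the two factors co-localize?** Peaks are reduced to their
   coverage summits, expanded to symmetric summit-centered windows of
   half-width *w* (window length 2*w*+1), and the union of the two window
   sets is partitioned into the connected components of its
   interval-overlap graph. Co-localization requires at least one shared
   base (touching intervals do not overlap, half-open arithmetic). A
   component containing windows from both sets is a *shared cluster*,
   counted once; the remainder are A-only / B-only.

2. **Are the shared loci enriched for a sequence motif?** Each window is
   scored binary motif-positive if it contains at least one instance of a
   degenerate consensus pattern over {A,C,G,T,N}; mismatches are counted
   only at fixed (non-N) positions, up to an allowance *m*. Counts in
   target (shared) versus background (A-only/B-only) windows form the
   2×2 table

   |            | positive | negative |
   |------------|----------|----------|
   | target     | a        | b        |
   | background | c        | d        |

   assessed with the two-sided Fisher exact test and the cross-product
   odds ratio (a·d)/(b·c). To show that enrichment is not a base-
   composition artefact, an exact dinucleotide-preserving permutation
   test (Altschul–Erickson Eulerian-trail shuffling) re-shuffles every
   target *n* times and reports the empirical p-value

   p = (r + 1) / (n + 1),

   where r counts permutations whose motif-positive count reaches the
   observed one. With the conventional n = 10,000 the attainable floor is
   1/10,001 ≈ 9.999×10⁻⁵.

Coverage metaprofile matrices (summit-centered at 1-bp bins, or regions
length-scaled to a fixed bin count) support heatmap-style visualisation,
and a synthetic-data generator emits genomes, peak/coverage fixtures and
motif-planted sequence sets with exact ground truth.

## Worked example

A fully synthetic run with known ground truth: 8 shared sites (planted
summit offsets ≤ 100 bp, each carrying the motif `GGTTCGAACC` at the
summit), 5 A-only and 4 B-only sites on a 0.5-Mb two-chromosome genome.

```r
library(MotifColoc)
library(GenomicRanges)

genome <- genGenome(c(chrI = 300000L, chrII = 200000L), gc = 0.38, seed = 42)
synth  <- genPeaksCoverage(genome, nShared = 8, nAOnly = 5, nBOnly = 4,
                           seed = 42)
# ... plant GGTTCGAACC at each shared summit (see vignette) ...

sl     <- seqLengths(genome)
peaksA <- peakSummits(granges(synth$peaksA), synth$trackA)
winA   <- expandWindows(as.character(seqnames(peaksA)),
                        mcols(peaksA)$summit, 150, sl)
# (same for set B)
coloc  <- classifyOverlap(winA, winB)
coloc
#> ColocResult: 17 clusters | shared 8, A_only 5, B_only 4

enr <- enrichMotif(targets, background, matchSpec("GGTTCGAACC", 1L))
enr
#> EnrichmentResult (Fisher exact, two-sided)
#>   target:     8 positive / 8 total
#>   background: 0 positive / 9 total
#>   odds ratio = Inf, p = 4.114e-05

permutationTest(targets, matchSpec("GGTTCGAACC", 1L), nPerm = 999, seed = 1)
#> PermutationResult: observed 8 positive | r = 0 of n = 999 | empirical p = 0.001
```

The Venn counts recover the planted design exactly; all 8 shared-locus
windows carry the motif while none of the 9 single-set windows does,
giving a Fisher p of 4.1×10⁻⁵; and no dinucleotide-preserving shuffle of
the targets reproduces the observed count, so the empirical p-value sits
at its floor 1/(999+1). `runFullAnalysis()` executes the same stages from
a YAML config and writes a JSON report plus BED/FASTA/TSV intermediates.

## Documentation

The methods vignette (`vignettes/motif-colocalization.Rmd`) describes the
model, its parameters and defaults, the numerical conventions
(tie-breaking, clipping, midpoint rounding, two-sided p definition), what
the synthetic generator does and does not emulate, and known limitations.
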