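#' @import methods
#' @importFrom S4Vectors Rle mcols mcols<- DataFrame runLength runValue
#' @importFrom IRanges IRanges RleList start end width findOverlaps
#' @importFrom GenomicRanges GRanges seqnames reduce granges countOverlaps
#' @importFrom utils head
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq
#' @useDynLib MotifColoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Per-chromosome piecewise-constant coverage
#'
#' A `CoverageTrack` stores a nonnegative, piecewise-constant signal per
#' chromosome (run-length encoded). Any position not covered by a segment
#' -- including positions on chromosomes absent from the track -- has the
#' value 0. Tracks are consumed as given (e.g. RPGC-normalized ChIP-seq
#' coverage); no normalization is performed here.
#'
#' @slot cov a [S4Vectors::RleList] of numeric runs, one element per
#'   chromosome, 1-based positions starting at 1.
#' @export
setClass("CoverageTrack", representation(cov = "RleList"))

setValidity("CoverageTrack", function(object) {
  nm <- names(object@cov)
  if (length(object@cov) > 0 &&
      (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    return("chromosome names must be unique and non-empty")
  for (i in seq_along(object@cov)) {
    v <- runValue(object@cov[[i]])
    if (any(is.na(v)) || any(v < 0))
      return("coverage values must be nonnegative and non-missing")
  }
  TRUE
})

#' Degenerate consensus pattern
#'
#' A pattern over the alphabet A, C, G, T, N. Only non-N ("fixed")
#' positions contribute to mismatch counting; N positions match any base.
#'
#' @slot pattern single uppercase string over \{A,C,G,T,N\}.
#' @slot fixedPositions integer positions (1-based) where the pattern is
#'   not N; derived from `pattern` at construction.
#' @export
setClass("DegeneratePattern",
         representation(pattern = "character", fixedPositions = "integer"))

setValidity("DegeneratePattern", function(object) {
  p <- object@pattern
  if (length(p) != 1L || is.na(p) || nchar(p) < 1L)
    return("pattern must be a single non-empty string")
  if (grepl("[^ACGTN]", p))
    return("pattern may only contain A, C, G, T, N")
  fp <- which(strsplit(p, "")[[1]] != "N")
  if (length(fp) == 0L)
    return("pattern must have at least one fixed (non-N) position")
  if (!identical(as.integer(fp), object@fixedPositions))
    return("fixedPositions inconsistent with pattern text")
  TRUE
})

#' Matching specification
#'
#' Couples a degenerate pattern with a mismatch allowance (counted at fixed
#' positions only) and a strand mode. `"forward"` scans the sequence as
#' given, `"revcomp"` scans its reverse complement, `"both"` is their
#' logical OR.
#'
#' @slot pattern a [DegeneratePattern-class].
#' @slot maxMismatch nonnegative integer, at most the number of fixed
#'   positions.
#' @slot strandMode one of `"forward"`, `"revcomp"`, `"both"`.
#' @export
setClass("MatchSpec",
         representation(pattern = "DegeneratePattern",
                        maxMismatch = "integer",
                        strandMode = "character"))

setValidity("MatchSpec", function(object) {
  if (!object@strandMode %in% c("forward", "revcomp", "both"))
    return("strandMode must be 'forward', 'revcomp' or 'both'")
  m <- object@maxMismatch
  if (length(m) != 1L || is.na(m) || m < 0L)
    return("maxMismatch must be a single nonnegative integer")
  if (m > length(object@pattern@fixedPositions))
    return("maxMismatch exceeds the number of fixed positions")
  TRUE
})

#' Co-localization of two window sets
#'
#' Result of clustering the union of two summit-window sets into the
#' connected components of their interval-overlap graph. A cluster is
#' *shared* iff it contains at least one window from each set; clusters
#' containing windows from a single set are *A_only* / *B_only*.
#'
#' @slot clusters a [GenomicRanges::GRanges] of merged cluster intervals
#'   with metadata columns `label` (shared/A_only/B_only), `nA`, `nB`.
#' @slot windowsA,windowsB the input windows, each with a `cluster`
#'   metadata column giving its cluster index.
#' @slot venn named integer vector `(shared, A_only, B_only)`: shared
#'   merged clusters counted once each; single-set windows counted per
#'   window (or per merged within-set cluster, see [classifyOverlap()]).
#' @export
setClass("ColocResult",
         representation(clusters = "GRanges",
                        windowsA = "GRanges",
                        windowsB = "GRanges",
                        venn = "integer"))

setValidity("ColocResult", function(object) {
  if (!identical(names(object@venn), c("shared", "A_only", "B_only")))
    return("venn must be named (shared, A_only, B_only)")
  if (any(object@venn < 0)) return("venn counts must be nonnegative")
  TRUE
})

#' Motif enrichment in target versus background windows
#'
#' Binary motif-positive counts arranged as the 2x2 table
#' \preformatted{
#'             positive  negative
#'   target        a         b
#'   background    c         d
#' }
#' with the cross-product odds ratio (a*d)/(b*c) and a two-sided Fisher
#' exact p-value.
#'
#' @slot table 2x2 integer matrix (rows target/background, columns
#'   positive/negative).
#' @slot oddsRatio nonnegative real, possibly `Inf`.
#' @slot pValue two-sided Fisher exact p-value in (0, 1].
#' @slot spec the [MatchSpec-class] used for scoring.
#' @export
setClass("EnrichmentResult",
         representation(table = "matrix", oddsRatio = "numeric",
                        pValue = "numeric", spec = "MatchSpec"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  if (!identical(dim(tb), c(2L, 2L))) return("table must be 2x2")
  if (any(tb < 0)) return("table cells must be nonnegative")
  if (sum(tb[1, ]) < 1 || sum(tb[2, ]) < 1)
    return("each of the target and background sets must be non-empty")
  TRUE
})

#' Dinucleotide-preserving permutation test result
#'
#' Observed motif-positive count among targets, the per-permutation counts
#' obtained by re-shuffling every target (exact dinucleotide-preserving
#' shuffle) and rescoring with the same matching criteria, and the
#' empirical p-value (r+1)/(n+1), where r counts permutations whose
#' positive count is greater than or equal to the observed count.
#'
#' @slot observed observed motif-positive count.
#' @slot nPerm number of permutations n.
#' @slot exceed exceedance count r (ties included).
#' @slot empiricalP exactly (r+1)/(n+1); never 0, minimum 1/(n+1).
#' @slot permCounts integer vector of per-permutation positive counts.
#' @export
setClass("PermutationResult",
         representation(observed = "integer", nPerm = "integer",
                        exceed = "integer", empiricalP = "numeric",
                        permCounts = "integer"))

setValidity("PermutationResult", function(object) {
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  if (object@exceed < 0L || object@exceed > object@nPerm)
    return("exceedance count must lie in [0, nPerm]")
  expP <- (object@exceed + 1) / (object@nPerm + 1)
  if (!isTRUE(all.equal(expP, object@empiricalP, tolerance = 0)))
    return("empiricalP must equal (r+1)/(n+1) exactly")
  TRUE
})

#' Coverage signal matrix
#'
#' Region-by-bin coverage values for heatmap-style visualisation; either
#' summit-centered at 1-bp bins (`mode = "summit_flank"`, 2*flank+1
#' columns) or length-scaled to a fixed bin count (`mode = "scaled"`).
#'
#' @slot values numeric matrix, rows = regions, all values >= 0.
#' @slot mode `"summit_flank"` or `"scaled"`.
#' @slot flank flank in bases (summit mode) or `NA`.
#' @slot nbins bin count (scaled mode) or `NA`.
#' @slot rowOrder permutation mapping current row order back to the input
#'   order (updated by [sortRowsByMean()]).
#' @export
setClass("SignalMatrix",
         representation(values = "matrix", mode = "character",
                        flank = "integer", nbins = "integer",
                        rowOrder = "integer"))

setValidity("SignalMatrix", function(object) {
  if (!object@mode %in% c("summit_flank", "scaled"))
    return("mode must be 'summit_flank' or 'scaled'")
  if (any(object@values < 0)) return("signal values must be nonnegative")
  if (object@mode == "summit_flank" &&
      ncol(object@values) != 2L * object@flank + 1L)
    return("summit_flank matrices must have 2*flank+1 columns")
  if (object@mode == "scaled" && ncol(object@values) != object@nbins)
    return("scaled matrices must have nbins columns")
  if (length(object@rowOrder) != nrow(object@values))
    return("rowOrder length must match the row count")
  TRUE
})
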