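#' Venn counts of a co-localization result
#'
#' @param x a [ColocResult-class].
#' @return named integer vector `(shared, A_only, B_only)`.
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' Merged overlap clusters
#'
#' @param x a [ColocResult-class].
#' @return a `GRanges` of merged cluster intervals with `label`, `nA`,
#'   `nB` metadata columns.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' Contingency table of an enrichment result
#'
#' @param x an [EnrichmentResult-class].
#' @return the 2x2 integer count matrix.
#' @export
setGeneric("contTable", function(x) standardGeneric("contTable"))

#' Two-sided Fisher p-value of an enrichment result
#'
#' @param x an [EnrichmentResult-class] or [PermutationResult-class].
#' @return for enrichment results the two-sided Fisher exact p-value; for
#'   permutation results the empirical p-value (r+1)/(n+1).
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Signal values of a matrix-like object
#'
#' @param x a [SignalMatrix-class].
#' @return the underlying numeric matrix.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' Sort matrix rows by row mean
#'
#' @param x a [SignalMatrix-class].
#' @param descending sort from high to low mean (default `TRUE`).
#' @param key optional second [SignalMatrix-class] with identical row
#'   count whose row means supply the sort key (e.g. order one factor's
#'   heatmap by the mean signal of another factor over the same regions).
#' @return a [SignalMatrix-class] with rows permuted; ties keep their
#'   original relative order and the applied permutation is recorded in
#'   the `rowOrder` slot.
#' @export
setGeneric("sortRowsByMean",
           function(x, descending = TRUE, key = NULL)
             standardGeneric("sortRowsByMean"))

setMethod("vennCounts", "ColocResult", function(x) x@venn)
setMethod("clusters", "ColocResult", function(x) x@clusters)
setMethod("contTable", "EnrichmentResult", function(x) x@table)
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)
setMethod("pValue", "PermutationResult", function(x) x@empiricalP)
setMethod("signalValues", "SignalMatrix", function(x) x@values)

setMethod("show", "DegeneratePattern", function(object) {
  cat("DegeneratePattern:", object@pattern,
      sprintf("(%d bp, %d fixed positions)\n", nchar(object@pattern),
              length(object@fixedPositions)))
})

setMethod("show", "MatchSpec", function(object) {
  cat("MatchSpec:", object@pattern@pattern,
      sprintf("| max mismatches %d (fixed positions only) | strand %s\n",
              object@maxMismatch, object@strandMode))
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack with %d chromosome(s)\n", length(object@cov)))
  for (nm in head(names(object@cov), 5)) {
    r <- object@cov[[nm]]
    cat(sprintf("  %s: length %d, %d runs, max %.4g\n", nm, length(r),
                length(runValue(r)), if (length(r)) max(runValue(r)) else 0))
  }
  if (length(object@cov) > 5) cat("  ...\n")
})

setMethod("show", "ColocResult", function(object) {
  v <- object@venn
  cat(sprintf(
    "ColocResult: %d clusters | shared %d, A_only %d, B_only %d\n",
    length(object@clusters), v[["shared"]], v[["A_only"]], v[["B_only"]]))
})

setMethod("show", "EnrichmentResult", function(object) {
  tb <- object@table
  cat("EnrichmentResult (Fisher exact, two-sided)\n")
  cat(sprintf("  target:     %d positive / %d total\n",
              tb[1, 1], sum(tb[1, ])))
  cat(sprintf("  background: %d positive / %d total\n",
              tb[2, 1], sum(tb[2, ])))
  cat(sprintf("  odds ratio = %.4g, p = %.4g\n",
              object@oddsRatio, object@pValue))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed %d positive | r = %d of n = %d | empirical p = %.4g\n",
    object@observed, object@exceed, object@nPerm, object@empiricalP))
})

setMethod("show", "SignalMatrix", function(object) {
  cat(sprintf("SignalMatrix (%s): %d regions x %d bins\n", object@mode,
              nrow(object@values), ncol(object@values)))
})
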