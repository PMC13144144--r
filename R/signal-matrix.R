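#' Summit-centered coverage matrix
#'
#' One row per summit; column j holds the coverage value at position
#' `summit - flank + j - 1` in 1-bp bins, for heatmap-style metaprofiles
#' over peak summits and their flanks. Positions beyond chromosome ends
#' contribute 0, matching the track's default-zero contract.
#'
#' @param chrom chromosome name per summit.
#' @param summit 1-based summit positions.
#' @param track a [CoverageTrack-class].
#' @param flank flank in bases on each side (default 1000).
#' @param rowNames optional row ids.
#' @return a [SignalMatrix-class] with `2*flank+1` columns.
#' @export
summitMatrix <- function(chrom, summit, track, flank = 1000L,
                         rowNames = NULL) {
  stopifnot(flank >= 0, length(chrom) == length(summit))
  flank <- as.integer(flank)
  vals <- t(vapply(seq_along(summit), function(i) {
    trackValues(track, chrom[i], summit[i] - flank, summit[i] + flank)
  }, numeric(2L * flank + 1L)))
  if (length(summit) == 1L) vals <- matrix(vals, nrow = 1L)
  rownames(vals) <- if (!is.null(rowNames)) rowNames else
    paste0(chrom, ":", summit)
  new("SignalMatrix", values = vals, mode = "summit_flank", flank = flank,
      nbins = NA_integer_, rowOrder = seq_along(summit))
}

#' Length-scaled coverage matrix
#'
#' Regions of varying length are scaled to a uniform axis of `nbins`
#' bins from start (S) to end (E): each region is split into `nbins`
#' contiguous base ranges as equal as possible (any remainder is spread
#' over the leftmost bins) and the bin value is the mean coverage over
#' its range. Regions shorter than `nbins` reuse single bases across
#' adjacent bins so no bin is ever empty.
#'
#' @param regions a `GRanges` of regions (length >= 1 each), taken as
#'   given (no strand-aware flipping).
#' @param track a [CoverageTrack-class].
#' @param nbins number of bins (>= 1).
#' @return a [SignalMatrix-class] with `nbins` columns.
#' @export
scaledRegionMatrix <- function(regions, track, nbins) {
  stopifnot(is(regions, "GRanges"), nbins >= 1)
  nbins <- as.integer(nbins)
  chrom <- as.character(seqnames(regions))
  vals <- t(vapply(seq_along(regions), function(i) {
    s <- start(regions)[i]; e <- end(regions)[i]
    v <- trackValues(track, chrom[i], s, e)
    len <- e - s + 1L
    if (len >= nbins) {
      base <- len %/% nbins
      extra <- len %% nbins
      sizes <- rep(base, nbins) + c(rep(1L, extra), rep(0L, nbins - extra))
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
    } else {
      # repeat single bases across bins, left-heavy, never empty
      idx <- floor(seq(0, len, length.out = nbins + 1L))
      starts <- pmin(idx[-(nbins + 1L)] + 1L, len)
      ends <- pmax(idx[-1L], starts)
    }
    vapply(seq_len(nbins),
           function(j) mean(v[starts[j]:ends[j]]), numeric(1))
  }, numeric(nbins)))
  if (length(regions) == 1L) vals <- matrix(vals, nrow = 1L)
  rownames(vals) <- if (!is.null(mcols(regions)$name))
    mcols(regions)$name else paste0(chrom, ":", start(regions))
  new("SignalMatrix", values = vals, mode = "scaled", flank = NA_integer_,
      nbins = nbins, rowOrder = seq_along(regions))
}

setMethod("sortRowsByMean", "SignalMatrix",
          function(x, descending = TRUE, key = NULL) {
  keyMat <- if (is.null(key)) x@values else signalValues(key)
  if (nrow(keyMat) != nrow(x@values))
    stop("key matrix must have the same number of rows")
  means <- rowMeans(keyMat)
  # order() is stable, so ties keep their original relative order
  ord <- order(if (descending) -means else means)
  new("SignalMatrix", values = x@values[ord, , drop = FALSE],
      mode = x@mode, flank = x@flank, nbins = x@nbins,
      rowOrder = x@rowOrder[ord])
})

#' Write a signal matrix as TSV
#'
#' @param x a [SignalMatrix-class].
#' @param path output path; first column holds the row id.
#' @return `path`, invisibly.
#' @export
writeSignalMatrix <- function(x, path) {
  df <- data.frame(region = rownames(x@values), x@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
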