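#' Peak summits from a coverage track
#'
#' The summit of a peak is the leftmost position attaining the maximum
#' coverage value inside the peak interval. If the track is zero over the
#' whole peak (including peaks on chromosomes absent from the track) the
#' interval midpoint is used as a deterministic fallback.
#'
#' @param peaks a `GRanges` of peak intervals.
#' @param track a [CoverageTrack-class].
#' @return `peaks` with a `summit` metadata column (1-based position
#'   within each peak).
#' @export
peakSummits <- function(peaks, track) {
  stopifnot(is(peaks, "GRanges"), is(track, "CoverageTrack"))
  chrom <- as.character(seqnames(peaks))
  summit <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    s <- start(peaks)[i]; e <- end(peaks)[i]
    v <- trackValues(track, chrom[i], s, e)
    if (all(v == 0)) {
      # midpoint fallback: floor((start0 + end0)/2) in 0-based half-open
      summit[i] <- (s - 1L + e) %/% 2L + 1L
    } else {
      summit[i] <- s + which.max(v) - 1L
    }
  }
  mcols(peaks)$summit <- summit
  peaks
}

#' Expand summits to symmetric windows
#'
#' Each summit becomes a window of half-width `w`: the summit base plus
#' `w` bases on each side (unclipped length 2w+1, keeping the summit
#' exactly central). Windows are clipped at chromosome boundaries.
#'
#' @param chrom chromosome name(s).
#' @param summit 1-based summit position(s).
#' @param w half-width in bases (>= 0); `w = 0` gives the summit base
#'   alone.
#' @param seqlens named vector of chromosome lengths (see
#'   [seqLengths()]).
#' @return a `GRanges` of windows with a `summit` metadata column.
#' @export
expandWindows <- function(chrom, summit, w, seqlens) {
  stopifnot(w >= 0, length(chrom) == length(summit))
  if (length(chrom) == 0L) return(GRanges())
  if (any(!chrom %in% names(seqlens)))
    stop("chromosome absent from seqlens")
  len <- unname(seqlens[chrom])
  if (any(summit < 1L) || any(summit > len))
    stop("summit outside its chromosome")
  gr <- GRanges(chrom, IRanges(pmax(1L, as.integer(summit - w)),
                               pmin(as.integer(len), as.integer(summit + w))))
  mcols(gr)$summit <- as.integer(summit)
  gr
}

#' Classify co-localization of two window sets
#'
#' The union of the two window sets is partitioned into the connected
#' components of its interval-overlap graph (computed by a sorted sweep
#' via [GenomicRanges::reduce()] with `min.gapwidth = 0`, so intervals
#' that merely touch do not overlap -- co-localization requires at least
#' one shared base). A component is labelled `shared` iff it contains at
#' least one window from each set, otherwise `A_only` / `B_only`.
#'
#' Venn counts follow the merged-cluster convention for shared loci
#' (each shared cluster counted once, preventing redundant counting of
#' partially overlapping signals). Single-set sides are counted per
#' window by default; `mergeWithinSet = TRUE` counts merged within-set
#' clusters instead.
#'
#' @param a,b `GRanges` window sets (sets A and B).
#' @param mergeWithinSet count A_only/B_only per merged within-set
#'   cluster rather than per window.
#' @return a [ColocResult-class].
#' @export
classifyOverlap <- function(a, b, mergeWithinSet = FALSE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  all <- c(granges(a), granges(b))
  cl <- reduce(all, min.gapwidth = 0L, ignore.strand = TRUE)
  hit <- findOverlaps(all, cl, minoverlap = 1L, ignore.strand = TRUE)
  memb <- integer(length(all))
  memb[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  membA <- memb[seq_along(a)]
  membB <- memb[seq_along(b) + length(a)]
  nA <- tabulate(membA, nbins = length(cl))
  nB <- tabulate(membB, nbins = length(cl))
  label <- ifelse(nA > 0 & nB > 0, "shared",
                  ifelse(nA > 0, "A_only", "B_only"))
  mcols(cl)$label <- label
  mcols(cl)$nA <- nA
  mcols(cl)$nB <- nB
  if (mergeWithinSet) {
    nAonly <- sum(label == "A_only")
    nBonly <- sum(label == "B_only")
  } else {
    nAonly <- sum(nA[label == "A_only"])
    nBonly <- sum(nB[label == "B_only"])
  }
  venn <- c(shared = sum(label == "shared"),
            A_only = as.integer(nAonly), B_only = as.integer(nBonly))
  outA <- a; mcols(outA)$cluster <- membA
  outB <- b; mcols(outB)$cluster <- membB
  new("ColocResult", clusters = cl, windowsA = outA, windowsB = outB,
      venn = venn)
}

#' Represent clusters by midpoint-centered windows
#'
#' Each merged cluster is represented by a window of half-width `w`
#' centered on the cluster midpoint (floor of the mean of the 0-based
#' half-open bounds; the half-base left bias on even-length clusters is
#' immaterial at w = 150 but keeps runs deterministic).
#'
#' @param cl a `GRanges` of cluster intervals (e.g. [clusters()]).
#' @param w half-width in bases (default 150).
#' @param seqlens named chromosome lengths for boundary clipping.
#' @return a `GRanges` of midpoint-centered windows (metadata preserved,
#'   `summit` holding the midpoint).
#' @export
clusterWindows <- function(cl, w = 150L, seqlens) {
  if (length(cl) == 0L) return(GRanges())
  mid0 <- (start(cl) - 1L + end(cl)) %/% 2L
  out <- expandWindows(as.character(seqnames(cl)), mid0 + 1L, w, seqlens)
  mcols(out) <- cbind(mcols(cl), mcols(out))
  out
}

#' Random control loci
#'
#' Draws `n` windows of exactly `width` bases uniformly over valid start
#' positions, with chromosomes weighted by their number of valid starts,
#' rejecting windows that overlap `exclude`. Used to show that observed
#' co-enrichment is not attributable to background signal.
#'
#' @param seqlens named chromosome lengths, or a `DNAStringSet` genome.
#' @param n number of loci.
#' @param width window width in bases (<= shortest chromosome).
#' @param seed integer seed; fixed seed gives identical output.
#' @param exclude optional `GRanges` that loci must not overlap.
#' @param maxTries rejection-sampling bound per locus drawn.
#' @return a `GRanges` of `n` windows, each of width `width`.
#' @export
randomLoci <- function(seqlens, n, width, seed, exclude = NULL,
                       maxTries = 1000L) {
  if (is(seqlens, "DNAStringSet")) seqlens <- seqLengths(seqlens)
  stopifnot(n >= 1, width >= 1)
  if (any(seqlens < width))
    stop("width exceeds the shortest chromosome")
  set.seed(seed)
  nvalid <- seqlens - width + 1L
  got <- 0L
  acc <- list()
  tries <- 0L
  while (got < n) {
    if (tries >= maxTries * n)
      stop("could not place ", n, " non-excluded loci after ",
           tries, " draws")
    k <- n - got
    chrom <- sample(names(seqlens), k, replace = TRUE,
                    prob = nvalid / sum(nvalid))
    s1 <- vapply(chrom, function(cm) sample.int(nvalid[[cm]], 1L),
                 integer(1))
    keep <- rep(TRUE, k)
    cand <- GRanges(chrom, IRanges(s1, width = width))
    if (!is.null(exclude) && length(exclude))
      keep <- countOverlaps(cand, exclude, ignore.strand = TRUE) == 0
    acc[[length(acc) + 1L]] <- data.frame(chrom = chrom[keep],
                                          start = s1[keep])
    got <- got + sum(keep)
    tries <- tries + k
  }
  df <- do.call(rbind, acc)[seq_len(n), ]
  picked <- GRanges(df$chrom, IRanges(df$start, width = width))
  mcols(picked)$name <- paste0("random_", seq_len(n))
  picked
}
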