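#' Generate a random genome
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`, split evenly within
#' the G/C and A/T pairs. This emulates only base composition, not the
#' repeat structure, chromatin landscape or origin architecture of a real
#' genome.
#'
#' @param lengths named integer vector of chromosome lengths (>= 1).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed; the genome is reproducible by seed.
#' @return a `DNAStringSet`.
#' @export
genGenome <- function(lengths, gc = 0.38, seed = 1L) {
  stopifnot(all(lengths >= 1), gc >= 0, gc <= 1)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  out <- DNAStringSet(seqs)
  names(out) <- names(lengths)
  out
}

randomSeq <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

#' Synthetic peak pairs with planted summits and coverage
#'
#' Plants `nShared` A/B peak pairs whose summits differ by at most `d`
#' bases, plus isolated A-only and B-only peaks, each at least `minGap`
#' bases from every other planted site. Each coverage track carries a
#' triangular signal with a strict unique maximum at the planted summit,
#' so [peakSummits()] recovers the planted summits exactly; and provided
#' `d <= 2*w` and `minGap > 2*w + 1`, [classifyOverlap()] on
#' `w`-expanded windows recovers the planted labels exactly.
#'
#' @param genome a `DNAStringSet` (only its chromosome lengths are used).
#' @param nShared,nAOnly,nBOnly planted counts per class.
#' @param peakWidth length-2 range of peak widths in bases.
#' @param minGap minimum distance between planted sites (> 2*w+1 for
#'   guaranteed isolation of the "only" classes).
#' @param d maximum planted summit offset within a shared pair
#'   (<= 2*w for guaranteed overlap after expansion).
#' @param w window half-width the guarantees refer to.
#' @param height,noise peak signal height and uniform baseline noise
#'   bound (noise < height/2 keeps the planted maximum strict).
#' @param seed integer seed.
#' @param maxTries placement retry bound.
#' @return a list with `peaksA`, `peaksB` (`GRanges` with planted
#'   `summit`), `trackA`, `trackB` ([CoverageTrack-class]) and `truth`
#'   (data.frame of planted sites: `label`, `chrom`, `summitA`,
#'   `summitB`).
#' @export
genPeaksCoverage <- function(genome, nShared = 5L, nAOnly = 3L,
                             nBOnly = 2L, peakWidth = c(200L, 400L),
                             minGap = 2000L, d = 100L, w = 150L,
                             height = 10, noise = 0, seed = 1L,
                             maxTries = 1000L) {
  stopifnot(d <= 2L * w, minGap > 2L * w + 1L, noise < height / 2)
  sl <- seqLengths(genome)
  set.seed(seed)
  nSites <- nShared + nAOnly + nBOnly
  margin <- max(peakWidth) + d + 2L
  if (any(sl < 2L * margin + 1L)) stop("chromosomes too short for peaks")

  # place site centers with pairwise distance >= minGap + margin
  centers <- data.frame(chrom = character(0), pos = integer(0))
  tries <- 0L
  while (nrow(centers) < nSites) {
    if (tries > maxTries * nSites)
      stop("could not place ", nSites, " sites with the requested gap")
    chrom <- sample(names(sl), 1L, prob = sl / sum(sl))
    pos <- sample((margin + 1L):(sl[[chrom]] - margin), 1L)
    same <- centers$chrom == chrom
    if (!any(same) || all(abs(centers$pos[same] - pos) >= minGap + 2L * margin))
      centers <- rbind(centers, data.frame(chrom = chrom, pos = pos))
    tries <- tries + 1L
  }
  label <- rep(c("shared", "A_only", "B_only"), c(nShared, nAOnly, nBOnly))

  mkPeak <- function(chrom, summit) {
    wd <- sample(peakWidth[1]:peakWidth[2], 1L)
    lo <- sample.int(wd - 2L, 1L)  # summit strictly inside
    start <- summit - lo
    data.frame(chrom = chrom, start = start, end = start + wd - 1L,
               summit = summit)
  }
  pa <- list(); pb <- list()
  truth <- data.frame(label = label, chrom = centers$chrom,
                      summitA = NA_integer_, summitB = NA_integer_)
  for (i in seq_len(nSites)) {
    cm <- centers$chrom[i]; ct <- centers$pos[i]
    if (label[i] != "B_only") {
      truth$summitA[i] <- ct
      pa[[length(pa) + 1L]] <- mkPeak(cm, ct)
    }
    if (label[i] != "A_only") {
      sb <- if (label[i] == "shared") ct + sample(seq(-d, d), 1L) else ct
      truth$summitB[i] <- sb
      pb[[length(pb) + 1L]] <- mkPeak(cm, sb)
    }
  }
  asGr <- function(lst) {
    df <- do.call(rbind, lst)
    GRanges(df$chrom, IRanges(df$start, df$end), summit = df$summit)
  }
  peaksA <- asGr(pa); peaksB <- asGr(pb)
  mcols(peaksA)$name <- paste0("peakA_", seq_along(peaksA))
  mcols(peaksB)$name <- paste0("peakB_", seq_along(peaksB))

  trackFor <- function(peaks) {
    seg <- lapply(seq_along(peaks), function(i) {
      s <- start(peaks)[i]; e <- end(peaks)[i]
      sm <- mcols(peaks)$summit[i]
      pos <- s:e
      v <- pmax(0, height - abs(pos - sm) * (height / (e - s + 1L)))
      if (noise > 0) v <- v + stats::runif(length(v), 0, noise)
      data.frame(chrom = as.character(seqnames(peaks))[i],
                 start0 = pos - 1L, end0 = pos, value = v)
    })
    seg <- do.call(rbind, seg)
    coverageTrack(seg$chrom, seg$start0, seg$end0, seg$value)
  }
  list(peaksA = peaksA, peaksB = peaksB,
       trackA = trackFor(peaksA), trackB = trackFor(peaksB),
       truth = truth)
}

#' Motif-planted target and background sequence sets
#'
#' Each target is independently designated motif-positive with
#' probability `piT` (background: `piB`). Designated-positive sequences
#' receive one planted pattern instance at a uniform offset, with a
#' mismatch count drawn from `mmProb` applied at random fixed positions;
#' designated-negative sequences are rejection-sampled until they contain
#' no qualifying match at mismatch level `rejectMismatch`. Designation-
#' then-rejection gives exact ground-truth flags at the cost of slight
#' composition distortion in negatives.
#'
#' @param pattern a [DegeneratePattern-class] or pattern string.
#' @param nTargets,nBackground set sizes.
#' @param piT,piB planted prevalence in targets / background.
#' @param windowLen window length (>= pattern length; 301 matches
#'   150-bp half-width windows).
#' @param gc background GC fraction.
#' @param mmProb probabilities of per-instance mismatch counts 0, 1, ...
#'   (default: always exact).
#' @param rejectMismatch mismatch level at which designated negatives
#'   must contain no match (default 0).
#' @param strandMode strand mode used for the negative rejection check.
#' @param seed integer seed.
#' @param maxTries rejection bound per negative sequence.
#' @return list with `targets`, `background` (named character vectors)
#'   and `truth` (data.frame: `set`, `planted`, `offset` (1-based, NA
#'   for negatives), `mismatches`).
#' @export
plantMotifSequences <- function(pattern, nTargets, nBackground,
                                piT = 0.5, piB = 0.05, windowLen = 301L,
                                gc = 0.38, mmProb = c(`0` = 1),
                                rejectMismatch = 0L,
                                strandMode = "forward",
                                seed = 1L, maxTries = 200L) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  L <- nchar(pattern@pattern)
  stopifnot(windowLen >= L, piT >= 0, piT <= 1, piB >= 0, piB <= 1)
  rejectSpec <- matchSpec(pattern, as.integer(rejectMismatch), strandMode)
  set.seed(seed)
  pc <- strsplit(pattern@pattern, "")[[1]]
  fp <- pattern@fixedPositions

  plantOne <- function(s, mm) {
    off <- sample.int(windowLen - L + 1L, 1L)
    inst <- pc
    # N positions stay whatever the background drew
    bg <- strsplit(s, "")[[1]]
    inst[inst == "N"] <- bg[off:(off + L - 1L)][inst == "N"]
    if (mm > 0) {
      hit <- fp[sample.int(length(fp), mm)]
      for (p in hit)
        inst[p] <- sample(setdiff(c("A", "C", "G", "T"), inst[p]), 1L)
    }
    substr(s, off, off + L - 1L) <- paste(inst, collapse = "")
    list(seq = s, offset = off, mm = mm)
  }
  drawSet <- function(n, pi, setName) {
    planted <- stats::runif(n) < pi
    seqs <- character(n)
    offs <- rep(NA_integer_, n)
    mms <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (planted[i]) {
        mm <- as.integer(sample(names(mmProb), 1L, prob = mmProb))
        pl <- plantOne(randomSeq(1L, windowLen, gc), mm)
        seqs[i] <- pl$seq; offs[i] <- pl$offset; mms[i] <- pl$mm
      } else {
        for (try in seq_len(maxTries)) {
          s <- randomSeq(1L, windowLen, gc)
          if (!isMotifPositive(s, rejectSpec)) break
          s <- NA_character_
        }
        if (is.na(s))
          stop("rejection sampling exceeded ", maxTries,
               " tries; pattern too permissive for the window")
        seqs[i] <- s
      }
    }
    names(seqs) <- paste0(setName, "_", seq_len(n))
    list(seqs = seqs,
         truth = data.frame(set = setName, planted = planted,
                            offset = offs, mismatches = mms))
  }
  tg <- drawSet(nTargets, piT, "target")
  bg <- drawSet(nBackground, piB, "background")
  list(targets = tg$seqs, background = bg$seqs,
       truth = rbind(tg$truth, bg$truth))
}

#' Composition-matched background by shuffling targets
#'
#' One exact dinucleotide-preserving shuffle per target, giving a
#' negative set whose pooled dinucleotide composition equals that of the
#' targets -- the control asking whether observed enrichment could be
#' explained by local nucleotide composition alone.
#'
#' @param targets sequence set (character or `DNAStringSet`).
#' @param seed integer seed.
#' @return named character vector of shuffled sequences.
#' @export
shuffleBackground <- function(targets, seed = 1L) {
  stopifnot(length(targets) >= 1L)
  out <- dinucShuffle(targets, seed = seed)
  names(out) <- paste0("shuffled_", seq_along(out))
  out
}
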