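#' Parse a degenerate consensus pattern
#'
#' Patterns are strings over A, C, G, T, N. N marks a degenerate position
#' that matches any base and never contributes to mismatch counting; all
#' other ("fixed") positions define the matching criteria. This supports
#' both exact k-mers (no N, e.g. the 10-bp near-palindromic core
#' `GGTTCGAACC`) and sparse consensus patterns such as an 18-bp pattern
#' with only 10 fixed positions.
#'
#' @param text pattern string; lowercase accepted.
#' @return a [DegeneratePattern-class].
#' @examples
#' parsePattern("GGNNCC")
#' @export
parsePattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(text)
  if (!nzchar(text)) stop("empty pattern")
  if (grepl("[^ACGTN]", text))
    stop("pattern may only contain A, C, G, T, N (only N is accepted as ",
         "a degenerate code)")
  fp <- which(strsplit(text, "")[[1]] != "N")
  if (length(fp) == 0L) stop("pattern must have at least one fixed position")
  new("DegeneratePattern", pattern = text, fixedPositions = as.integer(fp))
}

#' Build a matching specification
#'
#' @param pattern a [DegeneratePattern-class] or pattern string.
#' @param maxMismatch mismatch allowance, counted at fixed positions only
#'   (at most the number of fixed positions).
#' @param strandMode `"forward"` (default), `"revcomp"`, or `"both"`.
#'   Headline counts are conventionally forward-only; reverse-complement
#'   enrichment is reported separately.
#' @return a [MatchSpec-class].
#' @export
matchSpec <- function(pattern, maxMismatch = 0L,
                      strandMode = c("forward", "revcomp", "both")) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  strandMode <- match.arg(strandMode)
  new("MatchSpec", pattern = pattern,
      maxMismatch = as.integer(maxMismatch), strandMode = strandMode)
}

strandModeCode <- function(mode) {
  match(mode, c("forward", "revcomp", "both")) - 1L
}

#' Mismatches of a pattern at one offset
#'
#' Counts fixed pattern positions whose sequence character differs. N in
#' the pattern matches anything; N in the *sequence* at a fixed position
#' counts as a mismatch (conservative: assembly gaps cannot create
#' matches).
#'
#' @param seq a single sequence string.
#' @param pattern a [DegeneratePattern-class] or pattern string.
#' @param at 1-based alignment start in `seq` (must satisfy
#'   `1 <= at <= nchar(seq) - L + 1`).
#' @return integer mismatch count.
#' @examples
#' mismatchesAt("GATACC", "GGNNCC", 1)  # 1: position 2 only
#' @export
mismatchesAt <- function(seq, pattern, at) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(pattern@pattern)
  if (at < 1L || at > nchar(seq) - L + 1L)
    stop("offset out of range")
  sub <- substring(seq, at, at + L - 1L)
  sc <- strsplit(sub, "")[[1]]
  pc <- strsplit(pattern@pattern, "")[[1]]
  fp <- pattern@fixedPositions
  sum(sc[fp] != pc[fp])
}

#' Binary motif-positive scoring of sequence windows
#'
#' A sequence is motif-positive iff it contains at least one qualifying
#' instance of the pattern -- some offset (and, per the strand mode, some
#' strand) at which the number of fixed-position mismatches does not
#' exceed the allowance. Sequences shorter than the pattern are negative
#' (not an error).
#'
#' @param seqs character vector or `DNAStringSet` of sequence windows.
#' @param spec a [MatchSpec-class].
#' @return logical vector, one value per sequence.
#' @export
isMotifPositive <- function(seqs, spec) {
  stopifnot(is(spec, "MatchSpec"))
  seqs <- as.character(seqs)
  C_scan_positive(toupper(seqs), spec@pattern@pattern, spec@maxMismatch,
                  strandModeCode(spec@strandMode))
}

#' Count motif-positive sequences
#'
#' @inheritParams isMotifPositive
#' @return integer count of motif-positive sequences (order-independent;
#'   0 for an empty set).
#' @export
countPositive <- function(seqs, spec) {
  if (length(seqs) == 0L) return(0L)
  sum(isMotifPositive(seqs, spec))
}

#' Minimum mismatch count per sequence
#'
#' @inheritParams isMotifPositive
#' @param pattern a [DegeneratePattern-class] or pattern string.
#' @param strandMode strand mode as in [matchSpec()].
#' @return integer vector: the minimum fixed-position mismatch count over
#'   all offsets (and strands); `NA` for sequences shorter than the
#'   pattern.
#' @export
minMismatches <- function(seqs, pattern,
                          strandMode = c("forward", "revcomp", "both")) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  strandMode <- match.arg(strandMode)
  C_min_mismatches(toupper(as.character(seqs)), pattern@pattern,
                   strandModeCode(strandMode))
}

#' Per-sequence match report
#'
#' @inheritParams isMotifPositive
#' @return a data.frame with one row per sequence: `id`, `positive`,
#'   and for positive sequences the first qualifying match: `offset`
#'   (1-based start in the forward sequence), `strand` (`+`/`-`),
#'   `mismatches`.
#' @export
matchReport <- function(seqs, spec) {
  stopifnot(is(spec, "MatchSpec"))
  ch <- toupper(as.character(seqs))
  ids <- if (!is.null(names(seqs))) names(seqs) else
    paste0("seq", seq_along(ch))
  m <- C_best_match(ch, spec@pattern@pattern, spec@maxMismatch,
                    strandModeCode(spec@strandMode))
  data.frame(id = ids, positive = !is.na(m[, 1]),
             offset = m[, 1] + 1L,
             strand = c("+", "-")[m[, 2] + 1L],
             mismatches = m[, 3])
}

#' 2x2 contingency table of motif-positive counts
#'
#' @param a,b target motif-positive / motif-negative counts.
#' @param c,d background motif-positive / motif-negative counts.
#' @return a labelled 2x2 integer matrix.
#' @export
contingencyTable <- function(a, b, c, d) {
  tb <- matrix(as.integer(c(a, c, b, d)), nrow = 2,
               dimnames = list(set = c("target", "background"),
                               motif = c("positive", "negative")))
  if (any(tb < 0)) stop("contingency counts must be nonnegative")
  if (sum(tb[1, ]) < 1 || sum(tb[2, ]) < 1)
    stop("target and background sets must each be non-empty")
  tb
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities
#' (margins fixed) of all tables at least as extreme as the observed one,
#' i.e. with probability not exceeding the observed probability times
#' (1 + 1e-7); the tolerance guards against floating-point ties. This is
#' the dominant two-sided convention (as in [stats::fisher.test()]).
#'
#' @param table a 2x2 count matrix (e.g. from [contingencyTable()]).
#' @return p-value in (0, 1].
#' @examples
#' fisherTwoSided(contingencyTable(5, 0, 0, 5))  # 2/252
#' @export
fisherTwoSided <- function(table) {
  stopifnot(is.matrix(table), identical(dim(table), c(2L, 2L)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b; n2 <- c + d; k <- a + c
  if (m < 1 || n2 < 1)
    stop("a margin needed for the test is zero in both cells")
  if (k == 0 || b + d == 0) return(1)
  supp <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(supp, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Cross-product odds ratio of a 2x2 table
#'
#' @param table a 2x2 count matrix.
#' @param haldane add 0.5 to every cell first (Haldane-Anscombe
#'   correction; default off).
#' @return `(a*d)/(b*c)`; `Inf` when `b*c == 0` and `a*d > 0`; `NaN` when
#'   both products are 0.
#' @export
crossOddsRatio <- function(table, haldane = FALSE) {
  stopifnot(is.matrix(table), identical(dim(table), c(2L, 2L)))
  tb <- table + if (haldane) 0.5 else 0
  a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  if (b * c == 0) {
    if (a * d > 0) return(Inf) else return(NaN)
  }
  (a * d) / (b * c)
}

#' Motif enrichment of targets over background
#'
#' Scores both sequence sets as motif-positive/negative under one
#' matching specification, builds the 2x2 table, and reports the
#' cross-product odds ratio and two-sided Fisher exact p-value. No
#' multiple-testing adjustment is applied.
#'
#' @param targets,background sequence sets (character or `DNAStringSet`).
#' @param spec a [MatchSpec-class].
#' @param haldane use the Haldane-Anscombe corrected odds ratio.
#' @return an [EnrichmentResult-class].
#' @export
enrichMotif <- function(targets, background, spec, haldane = FALSE) {
  stopifnot(length(targets) >= 1L, length(background) >= 1L)
  a <- countPositive(targets, spec)
  c <- countPositive(background, spec)
  tb <- contingencyTable(a, length(targets) - a,
                         c, length(background) - c)
  new("EnrichmentResult", table = tb,
      oddsRatio = crossOddsRatio(tb, haldane = haldane),
      pValue = fisherTwoSided(tb), spec = spec)
}
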