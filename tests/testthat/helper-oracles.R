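# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own scanning/clustering code paths.

library(GenomicRanges)

random_seq <- function(len, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- if (length(alphabet) == 4)
    c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  else rep(1 / length(alphabet), length(alphabet))
  paste(sample(alphabet, len, replace = TRUE, prob = p), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# exhaustive scan over every offset (and strand): mismatches counted at
# fixed (non-N) pattern positions only
oracle_positive <- function(seq, pattern, max_mm,
                            strand = c("forward", "revcomp", "both")) {
  strand <- match.arg(strand)
  scan1 <- function(s, pat) {
    pc <- strsplit(pat, "")[[1]]
    fixed <- which(pc != "N")
    sc <- strsplit(s, "")[[1]]
    L <- length(pc)
    if (length(sc) < L) return(FALSE)
    for (o in 0:(length(sc) - L)) {
      mm <- sum(sc[o + fixed] != pc[fixed])
      if (mm <= max_mm) return(TRUE)
    }
    FALSE
  }
  fwd <- scan1(seq, pattern)
  if (strand == "forward") return(fwd)
  rc <- scan1(oracle_revcomp(seq), pattern)
  if (strand == "revcomp") rc else (fwd || rc)
}

# two-sided Fisher p by direct enumeration of the hypergeometric support,
# point probabilities from lchoose (independent of dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(m + n2, k)
  p <- exp(logp)
  pobs <- p[supp == a]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# all-pairs interval-overlap graph -> connected components via union-find
oracle_components <- function(gr) {
  n <- length(gr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ch <- as.character(seqnames(gr))
  s <- start(gr); e <- end(gr)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ch[i] == ch[j] && s[i] <= e[j] && s[j] <= e[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# per-base coverage lookup from the raw segment table
oracle_track_values <- function(segs, chrom, start1, end1) {
  out <- numeric(end1 - start1 + 1)
  rows <- segs[segs$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(rows))) {
    pos1 <- (rows$start0[r] + 1):rows$end0[r]
    hit <- pos1[pos1 >= start1 & pos1 <= end1]
    out[hit - start1 + 1] <- rows$value[r]
  }
  out
}

oracle_dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 2) return(table(character(0)))
  table(paste0(ch[-n], ch[-1]))
}
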