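# Coordinates in comments are BED-style (0-based, half-open) where they
# mirror the documented contracts; GRanges values are 1-based closed.

test_that("peak summits take the leftmost maximum with midpoint fallback", {
  # per-base values [0,0,5,5,1] over BED [0,5)
  tr <- coverageTrack(rep("c", 5), 0:4, 1:5, c(0, 0, 5, 5, 1))
  pk <- GRanges("c", IRanges(1, 5))
  expect_equal(mcols(peakSummits(pk, tr))$summit, 3L)  # 0-based 2

  # all-zero over BED [10,20) -> midpoint 15 (0-based)
  pk2 <- GRanges("c", IRanges(11, 20))
  empty <- coverageTrack(character(), integer(), integer(), numeric())
  expect_equal(mcols(peakSummits(pk2, empty))$summit, 16L)

  # constant 3.0 over BED [7,12) -> leftmost tie, 0-based 7
  tr3 <- coverageTrack("c", 7, 12, 3.0)
  pk3 <- GRanges("c", IRanges(8, 12))
  expect_equal(mcols(peakSummits(pk3, tr3))$summit, 8L)

  # chromosome absent from track behaves as all-zero, no error
  pk4 <- GRanges("other", IRanges(11, 20))
  expect_equal(mcols(peakSummits(pk4, tr))$summit, 16L)
})

test_that("window expansion is symmetric, clipped, and validated", {
  sl <- c(chr = 1000000L)
  w <- expandWindows("chr", 1001L, 150L, sl)  # 0-based summit 1000
  expect_equal(c(start(w) - 1L, end(w)), c(850L, 1151L))  # BED [850,1151)
  expect_equal(width(w), 301L)

  wl <- expandWindows("chr", 6L, 150L, sl)    # 0-based summit 5, left clip
  expect_equal(c(start(wl) - 1L, end(wl)), c(0L, 156L))

  w0 <- expandWindows("chr", 1001L, 0L, sl)   # +/-0 case
  expect_equal(width(w0), 1L)

  expect_error(expandWindows("chr", 0L, 10L, sl), "outside")
  expect_error(expandWindows("chr", 1000001L, 10L, sl), "outside")
})

test_that("one shared base means overlap; touching windows stay disjoint", {
  # A=[100,200), B=[199,300): 1-bp overlap -> one shared cluster
  a <- GRanges("c", IRanges(101, 200))
  b <- GRanges("c", IRanges(200, 300))
  r <- classifyOverlap(a, b)
  expect_equal(unname(vennCounts(r)), c(1L, 0L, 0L))
  expect_equal(c(start(clusters(r)) - 1L, end(clusters(r))), c(100L, 300L))

  # A=[100,200), B=[200,300): touching, not overlapping
  b2 <- GRanges("c", IRanges(201, 300))
  r2 <- classifyOverlap(a, b2)
  expect_equal(unname(vennCounts(r2)), c(0L, 1L, 1L))
})

test_that("shared clusters are counted once; every window joins one cluster", {
  # two A windows both overlapping one B window -> (1, 0, 0)
  a <- GRanges("c", IRanges(c(101, 181), c(200, 260)))
  b <- GRanges("c", IRanges(150, 240))
  r <- classifyOverlap(a, b)
  expect_equal(unname(vennCounts(r)), c(1L, 0L, 0L))

  # disjoint sets count per window
  a2 <- GRanges("c", IRanges(c(1, 1001, 2001), width = 100))
  b2 <- GRanges("c", IRanges(c(5001, 6001, 7001), width = 100))
  r2 <- classifyOverlap(a2, b2)
  expect_equal(unname(vennCounts(r2)), c(0L, 3L, 3L))

  # membership partition: A_only windows + A windows in shared clusters = |A|
  set.seed(30)
  a3 <- GRanges("c", IRanges(sample(1:50000, 80), width = 301))
  b3 <- GRanges("c", IRanges(sample(1:50000, 80), width = 301))
  r3 <- classifyOverlap(a3, b3)
  lab <- mcols(clusters(r3))$label
  inShared <- sum(mcols(clusters(r3))$nA[lab == "shared"])
  expect_equal(inShared + vennCounts(r3)[["A_only"]], 80L)
  expect_true(all(mcols(r3@windowsA)$cluster > 0))
})

test_that("sweep clustering equals the all-pairs connected-components oracle", {
  set.seed(77)
  for (rep in 1:30) {
    nA <- sample(10:60, 1); nB <- sample(10:60, 1)
    chroms <- c("c1", "c2")
    a <- GRanges(sample(chroms, nA, TRUE),
                 IRanges(sample(1:100000, nA), width = sample(50:500, nA, TRUE)))
    b <- GRanges(sample(chroms, nB, TRUE),
                 IRanges(sample(1:100000, nB), width = sample(50:500, nB, TRUE)))
    r <- classifyOverlap(a, b)
    allw <- c(granges(a), granges(b))
    comp <- oracle_components(allw)
    memb <- c(mcols(r@windowsA)$cluster, mcols(r@windowsB)$cluster)
    # same partition: cluster assignment must be a relabelling of oracle's
    expect_equal(length(unique(comp)), length(clusters(r)))
    expect_true(all(tapply(memb, comp, function(x) length(unique(x))) == 1))
    # venn counts from the oracle partition
    src <- rep(c("A", "B"), c(nA, nB))
    hasA <- tapply(src == "A", comp, any)
    hasB <- tapply(src == "B", comp, any)
    expect_equal(vennCounts(r)[["shared"]], sum(hasA & hasB))
    expect_equal(vennCounts(r)[["A_only"]],
                 sum(src == "A" & !(hasB[as.character(comp)])))
  }
})

test_that("enlarging the half-width never decreases the shared count", {
  set.seed(88)
  sl <- c(g = 200000L)
  sa <- sample(300:199700, 60); sb <- sample(300:199700, 60)
  prev <- -1L
  for (w in c(0L, 50L, 150L, 300L, 500L)) {
    r <- classifyOverlap(expandWindows(rep("g", 60), sa, w, sl),
                         expandWindows(rep("g", 60), sb, w, sl))
    expect_gte(vennCounts(r)[["shared"]], prev)
    prev <- vennCounts(r)[["shared"]]
  }
})

test_that("cluster windows are midpoint-centered and clipped", {
  sl <- c(c = 1000000L)
  cl <- GRanges("c", IRanges(101, 300))  # BED [100,300), midpoint 200
  cw <- clusterWindows(cl, 150L, sl)
  expect_equal(c(start(cw) - 1L, end(cw)), c(50L, 351L))

  cl2 <- GRanges("c", IRanges(1, 2))     # BED [0,2), midpoint 1
  cw2 <- clusterWindows(cl2, 150L, sl)
  expect_equal(c(start(cw2) - 1L, end(cw2)), c(0L, 152L))

  cl3 <- GRanges("c", IRanges(11, 11))   # BED [10,11), w = 0
  cw3 <- clusterWindows(cl3, 0L, sl)
  expect_equal(c(start(cw3) - 1L, end(cw3)), c(10L, 11L))
})

test_that("random loci are reproducible, excludable, and uniform", {
  sl <- c(c1 = 60000L, c2 = 40000L)
  l1 <- randomLoci(sl, 50, 301, seed = 1)
  l2 <- randomLoci(sl, 50, 301, seed = 1)
  expect_identical(start(l1), start(l2))
  expect_identical(as.character(seqnames(l1)), as.character(seqnames(l2)))
  expect_true(all(width(l1) == 301))

  whole <- GRanges(c("c1", "c2"), IRanges(1, c(60000, 40000)))
  expect_error(randomLoci(sl, 5, 301, seed = 1, exclude = whole,
                          maxTries = 20), "could not place")
  expect_error(randomLoci(c(s = 100L), 1, 301, seed = 1), "shortest")

  # start positions uniform over the genome (chi-square over 20 bins)
  sl2 <- c(g = 100000L)
  loci <- randomLoci(sl2, 10000, 301, seed = 42)
  bins <- cut(start(loci), breaks = seq(1, 100000 - 300, length.out = 21),
              include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})
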