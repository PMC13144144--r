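test_that("pattern parsing identifies fixed positions and rejects bad input", {
  p <- parsePattern("GGTTCGAACC")
  expect_equal(length(p@fixedPositions), 10L)
  p2 <- parsePattern("ggNNcc")
  expect_equal(p2@fixedPositions, c(1L, 2L, 5L, 6L))
  expect_error(parsePattern("NNN"), "fixed position")
  expect_error(parsePattern("ACGTX"), "only contain")
  expect_error(parsePattern(""), "empty")
})

test_that("mismatches are counted only at fixed positions", {
  expect_equal(mismatchesAt("GGTACC", "GGNNCC", 1), 0L)
  expect_equal(mismatchesAt("GATACC", "GGNNCC", 1), 1L)  # position 2 only
  expect_equal(mismatchesAt("NG", "GG", 1), 1L)          # sequence N mismatches
  expect_error(mismatchesAt("GG", "GGNNCC", 1), "out of range")
  expect_error(mismatchesAt("GGTACC", "GGNNCC", 2), "out of range")
})

test_that("match specs validate the mismatch allowance", {
  expect_error(matchSpec("GGNNCC", 5L), "exceeds")
  s <- matchSpec("GGTTCGAACC", 2L, "both")
  expect_s4_class(s, "MatchSpec")
})

test_that("binary scoring finds at least one qualifying instance", {
  spec0 <- matchSpec("GGTTCGAACC", 0L)
  expect_true(isMotifPositive("AAAGGTTCGAACCTTT", spec0))
  expect_false(isMotifPositive("AAAGA", spec0))  # shorter than the pattern
  expect_false(isMotifPositive("AAAGGTTCAAACCTTT", spec0))
  expect_true(isMotifPositive("AAAGGTTCAAACCTTT", matchSpec("GGTTCGAACC", 1L)))
  # revcomp-only match: GGGGGGGGGG matches CCCCCCCCCC on the other strand
  spec_c <- matchSpec("CCCCC", 0L, "revcomp")
  expect_true(isMotifPositive("AAGGGGGAA", spec_c))
  expect_false(isMotifPositive("AACCCCCAA", spec_c))
})

test_that("scanning equals the exhaustive brute-force oracle", {
  set.seed(19)
  patterns <- c("GGTTCGAACC", "GGNNCCNNTT", "ACGNNNNNNNNNNNNNNT")
  for (pat in patterns) for (mm in 0:2) for (mode in c("forward", "both")) {
    spec <- matchSpec(pat, mm, mode)
    seqs <- vapply(1:60, function(i)
      random_seq(sample(c(8, 30, 80), 1), gc = runif(1, 0.3, 0.7)), "")
    # spike in some planted and near-miss instances
    seqs <- c(seqs, paste0("AA", pat, "AA"), chartr("N", "A", pat))
    got <- isMotifPositive(seqs, spec)
    want <- vapply(seqs, oracle_positive, TRUE, pattern = pat,
                   max_mm = mm, strand = mode, USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("positive counts are order-independent and track prevalence", {
  spec <- matchSpec("GGTTCGAACC", 0L)
  seqs <- c("TTGGTTCGAACCTT", "AAAAAAAAAAAAAA", "GGTTCGAACC")
  expect_equal(countPositive(seqs, spec), 2L)
  expect_equal(countPositive(rev(seqs), spec), 2L)
  expect_equal(countPositive(character(0), spec), 0L)
  expect_equal(countPositive(c("GGT", "AAC"), spec), 0L)  # all too short

  set.seed(4)
  fix <- plantMotifSequences("GGTTCGAACC", nTargets = 400, nBackground = 1,
                             piT = 0.5, piB = 0, windowLen = 301, seed = 4)
  cnt <- countPositive(fix$targets, spec)
  expect_lt(abs(cnt - 200), 3 * sqrt(400 * 0.25))
})

test_that("raising the mismatch allowance never loses positives", {
  set.seed(23)
  seqs <- vapply(1:400, function(i) random_seq(301, gc = 0.45), "")
  for (pat in c("GGTTCGAACC", "GGNNTCNNGANNCCNNTT")) {
    prev <- rep(FALSE, length(seqs))
    for (mm in 0:2) {
      cur <- isMotifPositive(seqs, matchSpec(pat, mm))
      expect_true(all(cur[prev]))
      prev <- cur
    }
  }
})

test_that("two-sided Fisher p matches enumeration and known values", {
  expect_equal(fisherTwoSided(contingencyTable(5, 0, 0, 5)), 2 / 252)
  expect_equal(fisherTwoSided(contingencyTable(1, 1, 1, 1)), 1)
  expect_equal(fisherTwoSided(contingencyTable(2, 8, 2, 8)), 1)

  set.seed(12)
  for (i in 1:200) {
    tb <- matrix(rpois(4, 6), 2)
    if (sum(tb[1, ]) < 1 || sum(tb[2, ]) < 1) next
    expect_equal(fisherTwoSided(tb),
                 oracle_fisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    # agreement with the standard implementation
    expect_equal(fisherTwoSided(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant to transposing the table", {
  set.seed(13)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisherTwoSided(tb), fisherTwoSided(t(tb)), tolerance = 1e-12)
  }
})

test_that("Fisher test is conservative under the null", {
  set.seed(101)
  reject <- 0L
  nrep <- 400L
  for (i in seq_len(nrep)) {
    a <- rbinom(1, 50, 0.2); c <- rbinom(1, 50, 0.2)
    p <- fisherTwoSided(contingencyTable(a, 50 - a, c, 50 - c))
    if (p <= 0.05) reject <- reject + 1L
  }
  # binomial slack: 0.05 + 3 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(reject / nrep, 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("cross-product odds ratio handles zero cells and Haldane", {
  expect_equal(crossOddsRatio(contingencyTable(53, 47, 9, 91)), 4823 / 423)
  expect_equal(round(crossOddsRatio(contingencyTable(53, 47, 9, 91))), 11)
  expect_equal(crossOddsRatio(contingencyTable(1, 1, 1, 1)), 1)
  expect_identical(crossOddsRatio(contingencyTable(5, 0, 0, 5)), Inf)
  expect_equal(crossOddsRatio(contingencyTable(5, 0, 0, 5), haldane = TRUE),
               (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("enrichment of planted targets is detected with correct table margins", {
  fix <- plantMotifSequences("GGTTCGAACC", nTargets = 150, nBackground = 150,
                             piT = 0.6, piB = 0.02, windowLen = 301, seed = 9)
  spec <- matchSpec("GGTTCGAACC", 0L)
  enr <- enrichMotif(fix$targets, fix$background, spec)
  tb <- contTable(enr)
  expect_equal(sum(tb[1, ]), 150)
  expect_equal(sum(tb[2, ]), 150)
  expect_gt(enr@oddsRatio, 1)
  expect_lt(pValue(enr), 0.01)
})

test_that("the match report locates first qualifying instances", {
  spec <- matchSpec("GGTTCGAACC", 0L, "both")
  rep <- matchReport(c(x = "AAAGGTTCGAACC", y = "TTTTTTTTTTTT"), spec)
  expect_equal(rep$positive, c(TRUE, FALSE))
  expect_equal(rep$offset[1], 4L)
  expect_equal(rep$strand[1], "+")
  expect_true(is.na(rep$offset[2]))
})
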