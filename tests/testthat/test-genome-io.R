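test_that("FASTA reading normalizes case and collapses non-ACGT to N", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", ">c2 description", "ACRT"), tf)
  g <- readGenomeFasta(tf)
  expect_identical(names(g), c("chr1", "c2"))
  expect_identical(as.character(g[["chr1"]]), "ACGT")
  expect_identical(as.character(g[["c2"]]), "ACNT")
})

test_that("FASTA format errors are caught", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c", "ACGT", ">c", "TTTT"), tf)
  expect_error(readGenomeFasta(tf), "duplicate")
  writeLines(c(">a", "ACGT", ">empty", "", ">b", "GG"), tf)
  expect_error(readGenomeFasta(tf), "empty")
})

test_that("FASTA round-trips through write and read", {
  g <- genGenome(c(chrA = 500L, chrB = 120L), gc = 0.45, seed = 7)
  tf <- withr::local_tempfile(fileext = ".fa")
  writeGenomeFasta(g, tf)
  g2 <- readGenomeFasta(tf)
  expect_identical(as.character(g2), as.character(g))
})

test_that("BED dialects parse 0-based half-open coordinates", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", tf)
  gr <- readPeaksBed(tf, "bed3")
  expect_equal(start(gr), 11L)
  expect_equal(end(gr), 20L)
  expect_null(mcols(gr)$summit)

  writeLines("chr1\t10\t20\tp1\t0\t+\t14", tf)
  gr <- readPeaksBed(tf, "summit_col")
  expect_equal(mcols(gr)$summit, 15L)  # absolute 0-based 14
  expect_equal(mcols(gr)$name, "p1")
})

test_that("BED format errors are caught", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", tf)
  expect_error(readPeaksBed(tf, "bed3"), "start >= end")
  writeLines("chr1\t-5\t10", tf)
  expect_error(readPeaksBed(tf, "bed3"), "negative")
  writeLines("chr1\tten\t20", tf)
  expect_error(readPeaksBed(tf, "bed3"), "non-integer")
})

test_that("peak lists round-trip through BED with summit column", {
  sl <- c(chr1 = 10000L)
  gr <- expandWindows(rep("chr1", 3), c(500L, 2000L, 9990L), 150L, sl)
  mcols(gr)$name <- paste0("w", 1:3)
  mcols(gr)$score <- c(1, 2, 3)
  tf <- withr::local_tempfile(fileext = ".bed")
  writePeaksBed(gr, tf, summits = TRUE)
  back <- readPeaksBed(tf, "summit_col")
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$summit, mcols(gr)$summit)
})

test_that("bedGraph queries return segment values and default zero", {
  tf <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("c\t0\t5\t2.0", tf)
  tr <- readBedGraph(tf)
  expect_equal(trackValues(tr, "c", 4, 4), 2.0)  # 0-based position 3
  expect_equal(trackValues(tr, "c", 8, 8), 0)    # uncovered
  expect_equal(trackValues(tr, "missing", 1, 3), c(0, 0, 0))
})

test_that("bedGraph format errors are caught", {
  tf <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("c\t0\t5\t1", "c\t3\t8\t1"), tf)
  expect_error(readBedGraph(tf), "overlap")
  writeLines("c\t0\t5\t-1", tf)
  expect_error(readBedGraph(tf), "negative")
})

test_that("coverage queries agree with brute-force per-base expansion", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    starts <- sort(sample(0:9500, n))
    ends <- pmin(starts + sample(1:400, n, replace = TRUE),
                 c(starts[-1], 10000L))
    keep <- ends > starts
    segs <- data.frame(chrom = "c", start0 = starts[keep],
                       end0 = ends[keep],
                       value = round(runif(sum(keep), 0, 10), 3))
    tr <- coverageTrack(segs$chrom, segs$start0, segs$end0, segs$value)
    expect_equal(trackValues(tr, "c", 1, 10000),
                 oracle_track_values(segs, "c", 1, 10000))
  }
})

test_that("coverage tracks round-trip through bedGraph on the query contract", {
  set.seed(5)
  starts <- c(0, 100, 250)
  segs <- data.frame(chrom = "c", start0 = starts, end0 = starts + 50,
                     value = c(1.5, 0.25, 3))
  tr <- coverageTrack(segs$chrom, segs$start0, segs$end0, segs$value)
  tf <- withr::local_tempfile(fileext = ".bedgraph")
  writeBedGraph(tr, tf)
  tr2 <- readBedGraph(tf)
  expect_equal(trackValues(tr2, "c", 1, 400), trackValues(tr, "c", 1, 400))
})

test_that("revComp matches hand values and is an involution", {
  expect_identical(revComp("GGTTCGAACC"), "GGTTCGAACC")  # own revcomp
  expect_identical(revComp("A"), "T")
  expect_identical(revComp("AN"), "NT")
  expect_error(revComp("ACGU"), "outside")
  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(sample(1:80, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(revComp(revComp(s)), s)
    expect_identical(revComp(s), oracle_revcomp(s))
  }
})

test_that("window sequences extract correctly from the genome", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  gr <- GRanges("chr1", IRanges(3, 6))
  expect_identical(as.character(extractWindowSeqs(g, gr)[[1]]), "GTAC")
  expect_error(extractWindowSeqs(g, GRanges("chr2", IRanges(1, 2))),
               "absent")
  expect_error(extractWindowSeqs(g, GRanges("chr1", IRanges(8, 12))),
               "beyond")
})
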