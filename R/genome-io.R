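#' Read a genome (or window set) from FASTA
#'
#' Reads FASTA records into a [Biostrings::DNAStringSet], normalising the
#' sequences to the working alphabet: lowercase letters are uppercased and
#' every character outside A/C/G/T is mapped to N. Mapping to N rather than
#' erroring lets real genomes (ambiguity codes, gaps) parse; an N in a
#' sequence later counts as a mismatch at any fixed pattern position, so
#' assembly gaps can never create motif matches.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, record order preserved, names taken from the
#'   first whitespace-delimited token of each header.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtRYacgt"), tf)
#' readGenomeFasta(tf)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- readDNAStringSet(path, format = "fasta")
  names(ss) <- sub("\\s.*$", "", names(ss))
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  if (any(!nzchar(names(ss)))) stop("FASTA record with empty header")
  if (anyDuplicated(names(ss)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(ss)[duplicated(names(ss))]), collapse = ", "))
  if (any(width(ss) == 0L))
    stop("empty FASTA record(s): ",
         paste(names(ss)[width(ss) == 0L], collapse = ", "))
  normalizeAlphabet(ss)
}

# uppercase and collapse everything outside ACGT to N
normalizeAlphabet <- function(ss) {
  ch <- toupper(as.character(ss))
  ch <- gsub("[^ACGT]", "N", ch)
  out <- DNAStringSet(ch)
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome a `DNAStringSet`.
#' @return named integer vector of sequence lengths.
#' @export
seqLengths <- function(genome) {
  stats::setNames(width(genome), names(genome))
}

#' Reverse complement over the \{A,C,G,T,N\} alphabet
#'
#' N is self-complementary. The 10-mer core motif reported at shared
#' ORC/RPA loci, `GGTTCGAACC`, is its own reverse complement.
#'
#' @param seq character vector (or `DNAStringSet`) of sequences over
#'   \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @examples
#' revComp("GGTTCGAACC")
#' @export
revComp <- function(seq) {
  if (is(seq, "XStringSet") || is(seq, "XString"))
    seq <- as.character(seq)
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence contains characters outside A, C, G, T, N")
  vapply(seq, function(s) {
    if (!nchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## ---- BED peaks ----------------------------------------------------------

#' Read peaks from a BED-like file
#'
#' Coordinates on disk are BED-native (0-based, half-open); in memory they
#' become 1-based closed `GRanges` ranges, the Bioconductor convention.
#' The `summit_col` dialect carries a 7th column holding an absolute
#' 0-based summit position (our extension for passing computed summits
#' between pipeline stages); it is stored 1-based in the `summit`
#' metadata column.
#'
#' @param path path to a tab-separated BED3/BED6(+summit) file.
#' @param dialect `"bed3"`, `"bed6"` or `"summit_col"`.
#' @return a `GRanges`; `name`/`score` metadata for bed6+, `summit`
#'   (1-based) for `summit_col`.
#' @export
readPeaksBed <- function(path, dialect = c("bed3", "bed6", "summit_col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, summit_col = 7L)
  if (length(lines) == 0L)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("line %d has %d field(s); dialect '%s' needs %d",
                 which(nf < need)[1], nf[nf < need][1], dialect, need))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parseIntCol(fields, 2L, "start")
  end0 <- parseIntCol(fields, 3L, "end")
  if (any(start0 < 0L)) stop("negative start coordinate in ", path)
  if (any(start0 >= end0))
    stop(sprintf("interval with start >= end at line %d of %s",
                 which(start0 >= end0)[1], path))
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (dialect %in% c("bed6", "summit_col")) {
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    mcols(gr)$score <- score
  }
  if (dialect == "summit_col") {
    summit0 <- parseIntCol(fields, 7L, "summit")
    if (any(summit0 < start0 | summit0 >= end0))
      stop("summit outside its peak interval in ", path)
    mcols(gr)$summit <- summit0 + 1L
  }
  gr
}

parseIntCol <- function(fields, j, what) {
  raw <- vapply(fields, `[[`, "", j)
  v <- suppressWarnings(as.integer(raw))
  if (any(is.na(v)))
    stop(sprintf("non-integer %s coordinate: '%s'", what, raw[is.na(v)][1]))
  v
}

#' Write ranges as BED
#'
#' Emits 0-based, half-open coordinates. With `summits = TRUE` and a
#' `summit` metadata column present, a 7th column holds the absolute
#' 0-based summit (the `summit_col` dialect of [readPeaksBed()]).
#'
#' @param gr a `GRanges`; optional `name`/`score`/`summit` metadata.
#' @param path output path.
#' @param summits write the summit column when available.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(gr, path, summits = FALSE) {
  n <- length(gr)
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    paste0("region_", seq_len(max(n, 0)))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc, strand = ".")
  if (summits) {
    if (is.null(mcols(gr)$summit))
      stop("summits = TRUE but no 'summit' metadata column")
    df$summit <- mcols(gr)$summit - 1L
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- bedGraph coverage --------------------------------------------------

#' Build a coverage track from segments
#'
#' @param chrom,start0,end0,value parallel vectors of segments; `start0`
#'   and `end0` are 0-based half-open as in bedGraph. Segments on a
#'   chromosome must be non-overlapping; values must be nonnegative.
#' @return a [CoverageTrack-class].
#' @export
coverageTrack <- function(chrom, start0, end0, value) {
  if (length(chrom) == 0L)
    return(new("CoverageTrack", cov = RleList(compress = FALSE)))
  if (any(value < 0)) stop("negative coverage value")
  if (any(start0 < 0)) stop("negative segment coordinate")
  if (any(start0 >= end0)) stop("segment with start >= end")
  covs <- lapply(split(seq_along(chrom), chrom), function(ii) {
    o <- ii[order(start0[ii])]
    s <- start0[o]; e <- end0[o]; v <- value[o]
    if (length(o) > 1L && any(e[-length(e)] > s[-1L]))
      stop("overlapping coverage segments on chromosome ", chrom[o[1]])
    # interleave zero gaps with segment runs
    gap <- c(s[1], s[-1L] - e[-length(e)])
    runs <- rbind(gap, e - s)
    vals <- rbind(0, v)
    keep <- as.vector(runs) > 0
    Rle(as.vector(vals)[keep], as.vector(runs)[keep])
  })
  new("CoverageTrack", cov = RleList(covs, compress = FALSE))
}

#' Read a bedGraph coverage track
#'
#' Four tab- or space-separated columns: chrom, start (0-based), end
#' (half-open), value. Overlapping segments or negative values are format
#' errors; any position not covered by a segment queries as 0.
#'
#' @param path path to a bedGraph file.
#' @return a [CoverageTrack-class].
#' @export
readBedGraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(coverageTrack(character(), integer(), integer(), numeric()))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4L))
    stop("bedGraph line with fewer than 4 fields in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parseIntCol(fields, 2L, "start")
  end0 <- parseIntCol(fields, 3L, "end")
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (any(is.na(value))) stop("non-numeric coverage value in ", path)
  coverageTrack(chrom, start0, end0, value)
}

#' Write a coverage track as bedGraph
#'
#' Only non-zero runs are emitted; zero runs are implicit under the
#' default-zero query contract.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  rows <- lapply(names(track@cov), function(nm) {
    r <- track@cov[[nm]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)  # 0-based
    v <- runValue(r)
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = starts[keep], end = ends[keep],
               value = v[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Query coverage values at base resolution
#'
#' @param track a [CoverageTrack-class].
#' @param chrom chromosome name; a chromosome absent from the track reads
#'   as all-zero.
#' @param start1,end1 1-based closed positions; positions outside the
#'   track's extent (including non-positive ones) read as 0.
#' @return numeric vector of length `end1 - start1 + 1`.
#' @export
trackValues <- function(track, chrom, start1, end1) {
  stopifnot(is(track, "CoverageTrack"), end1 >= start1)
  n <- end1 - start1 + 1L
  out <- numeric(n)
  if (!chrom %in% names(track@cov)) return(out)
  r <- track@cov[[chrom]]
  lo <- max(start1, 1L)
  hi <- min(end1, length(r))
  if (hi >= lo)
    out[(lo - start1 + 1L):(hi - start1 + 1L)] <- as.numeric(r[lo:hi])
  out
}

#' Extract window sequences from a genome
#'
#' @param genome a `DNAStringSet`.
#' @param gr a `GRanges` of windows lying within the genome.
#' @return a `DNAStringSet`, one normalized sequence per window, named by
#'   the window `name` metadata when present.
#' @export
extractWindowSeqs <- function(genome, gr) {
  chrom <- as.character(seqnames(gr))
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad))
    stop("chromosome(s) absent from genome: ", paste(bad, collapse = ", "))
  sl <- seqLengths(genome)
  if (any(start(gr) < 1L) || any(end(gr) > sl[chrom]))
    stop("window extends beyond its chromosome")
  out <- DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i]))
  }, character(1)))
  names(out) <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
                else paste0("w", seq_along(gr))
  out
}
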