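#' Read a pipeline run configuration
#'
#' Plain-text key-value configuration in YAML (or JSON, a YAML subset).
#' Recognised keys: `peaks_a`, `peaks_b`, `track_a`, `track_b`, `genome`
#' (paths), `patterns` (one or more pattern strings), `w` (window
#' half-width, bases), `max_mismatch`, `strand_mode`, `n_perm`, `seed`,
#' `background` (`both`/`A_only`/`B_only`), `out_dir`. Referenced files
#' must exist. Window extraction parameters are always explicit in the
#' config -- no width is silently applied.
#'
#' @param path path to the configuration file.
#' @return a named list with defaults filled in, suitable for
#'   [runFullAnalysis()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  defaults <- list(w = 150L, max_mismatch = 0L, strand_mode = "forward",
                   n_perm = 10000L, seed = 1L, background = "both",
                   out_dir = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  needed <- c("peaks_a", "peaks_b", "track_a", "track_b", "genome",
              "patterns")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  for (k in c("peaks_a", "peaks_b", "track_a", "track_b", "genome"))
    if (!file.exists(cfg[[k]]))
      stop("config references a missing file (", k, "): ", cfg[[k]])
  if (!cfg$background %in% c("both", "A_only", "B_only"))
    stop("background must be 'both', 'A_only' or 'B_only'")
  cfg$w <- as.integer(cfg$w)
  cfg$max_mismatch <- as.integer(cfg$max_mismatch)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full co-localization and motif-enrichment analysis
#'
#' Executes the stages in order: peak summits from coverage, symmetric
#' window expansion at half-width `w`, overlap classification into
#' shared / A-only / B-only clusters, representation of shared clusters
#' by midpoint-centered `w`-windows (the target set), extraction of
#' target and background window sequences, and per-pattern enrichment
#' (two-sided Fisher exact test, cross-product odds ratio) plus the
#' dinucleotide-preserving permutation test. The background is the union
#' of A-only and B-only windows by default (`background = "both"`),
#' controlling for assay-specific biases from either side.
#'
#' Identical config and seed give identical reports; the report carries
#' no timestamps for that reason (logging is the caller's concern).
#'
#' @param config a config list ([readRunConfig()]) or path to a config
#'   file.
#' @return the analysis report (named list); when `out_dir` is set, the
#'   report is also written as `report.json` together with BED/TSV
#'   intermediates (`windows_a.bed`, `windows_b.bed`, `clusters.bed`,
#'   `targets.fa`, `background.fa`, `venn.tsv`).
#' @export
runFullAnalysis <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- validateRunConfig(config)

  genome <- stageTry("read_genome", readGenomeFasta(cfg$genome))
  sl <- seqLengths(genome)
  peaksA <- stageTry("read_peaks_a", readPeaksBed(cfg$peaks_a, "bed3"))
  peaksB <- stageTry("read_peaks_b", readPeaksBed(cfg$peaks_b, "bed3"))
  trackA <- stageTry("read_track_a", readBedGraph(cfg$track_a))
  trackB <- stageTry("read_track_b", readBedGraph(cfg$track_b))

  peaksA <- stageTry("summits_a", peakSummits(peaksA, trackA))
  peaksB <- stageTry("summits_b", peakSummits(peaksB, trackB))
  winA <- stageTry("windows_a", expandWindows(
    as.character(seqnames(peaksA)), mcols(peaksA)$summit, cfg$w, sl))
  winB <- stageTry("windows_b", expandWindows(
    as.character(seqnames(peaksB)), mcols(peaksB)$summit, cfg$w, sl))

  coloc <- stageTry("classify_overlap", classifyOverlap(winA, winB))
  cl <- clusters(coloc)
  shared <- cl[mcols(cl)$label == "shared"]
  if (length(shared) == 0L)
    stop("pipeline stage 'targets' failed: no shared clusters found")
  targetsGr <- stageTry("targets", clusterWindows(shared, cfg$w, sl))
  bgLabels <- switch(cfg$background,
                     both = c("A_only", "B_only"),
                     A_only = "A_only", B_only = "B_only")
  bgGr <- c(coloc@windowsA[mcols(cl)$label[mcols(coloc@windowsA)$cluster]
                           %in% intersect(bgLabels, "A_only")],
            coloc@windowsB[mcols(cl)$label[mcols(coloc@windowsB)$cluster]
                           %in% intersect(bgLabels, "B_only")])
  if (length(bgGr) == 0L)
    stop("pipeline stage 'background' failed: empty background set")

  targetSeqs <- stageTry("extract_targets",
                         extractWindowSeqs(genome, targetsGr))
  bgSeqs <- stageTry("extract_background", extractWindowSeqs(genome, bgGr))

  patterns <- as.character(cfg$patterns)
  perPattern <- lapply(patterns, function(p) {
    spec <- matchSpec(p, cfg$max_mismatch, cfg$strand_mode)
    enr <- stageTry(paste0("enrich:", p),
                    enrichMotif(targetSeqs, bgSeqs, spec))
    perm <- stageTry(paste0("permtest:", p),
                     permutationTest(targetSeqs, spec,
                                     nPerm = cfg$n_perm, seed = cfg$seed))
    tb <- contTable(enr)
    list(pattern = p,
         table = list(a = tb[1, 1], b = tb[1, 2],
                      c = tb[2, 1], d = tb[2, 2]),
         odds_ratio = crossOddsRatio(tb),
         fisher_p = pValue(enr),
         permutation = list(observed = perm@observed, n = perm@nPerm,
                            r = perm@exceed, empirical_p = perm@empiricalP))
  })
  names(perPattern) <- patterns

  report <- list(
    config = cfg[order(names(cfg))],
    n_windows_a = length(winA), n_windows_b = length(winB),
    venn = as.list(vennCounts(coloc)),
    n_targets = length(targetSeqs), n_background = length(bgSeqs),
    enrichment = perPattern,
    versions = list(MotifColoc =
      as.character(utils::packageVersion("MotifColoc")),
      R = paste(R.version$major, R.version$minor, sep = ".")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$out_dir, f)
    writePeaksBed(winA, out("windows_a.bed"), summits = TRUE)
    writePeaksBed(winB, out("windows_b.bed"), summits = TRUE)
    clOut <- cl
    mcols(clOut)$name <- mcols(cl)$label
    writePeaksBed(clOut, out("clusters.bed"))
    writeGenomeFasta(targetSeqs, out("targets.fa"))
    writeGenomeFasta(bgSeqs, out("background.fa"))
    vn <- vennCounts(coloc)
    utils::write.table(
      data.frame(class = names(vn), count = as.integer(vn)),
      out("venn.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}
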