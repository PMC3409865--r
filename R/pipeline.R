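#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run.  With `fastq = NULL` the
#' synthetic generator supplies the two libraries; otherwise `fastq` names
#' two FASTQ files (control first).
#'
#' @param outputDir directory for result tables and the manifest.
#' @param seed master seed; every stochastic step derives its seed from it.
#' @param totalReads named reads-per-group vector for the generator.
#' @param thresholds read-count thresholds of the accounting tables.
#' @param log2Threshold |log2| differential-expression cut.
#' @param mfeThreshold hairpin MFE pass threshold (kcal/mol, strict).
#' @param adapter3 3' adapter; `minMatch`, `maxMismatch`, `searchStart`
#'   are the trimming parameters.
#' @param minMatch,maxMismatch,searchStart adapter-scan parameters.
#' @param alternativeFraction fraction of degradome tags at non-canonical
#'   positions.
#' @param fastq optional named character vector of FASTQ paths.
#' @return a `list` with class `srnaRunConfig`.
#' @export
pipelineConfig <- function(outputDir = tempfile("srnarun"), seed = 1L,
                           totalReads = c(control = 100000L,
                                          transgenic = 80000L),
                           thresholds = c(1L, 4L, 10L), log2Threshold = 1,
                           mfeThreshold = -18,
                           adapter3 = ADAPTER3_DEFAULT, minMatch = 10L,
                           maxMismatch = 1L, searchStart = 18L,
                           alternativeFraction = 0, fastq = NULL) {
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 totalReads = totalReads, thresholds = thresholds,
                 log2Threshold = log2Threshold, mfeThreshold = mfeThreshold,
                 adapter3 = adapter3, minMatch = minMatch,
                 maxMismatch = maxMismatch, searchStart = searchStart,
                 alternativeFraction = alternativeFraction, fastq = fastq),
            class = "srnaRunConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic read generation (or FASTQ ingest),
#' preprocessing (artifact filter, adapter trimming, collapsing, size
#' tables), the chloroplast partition, the classification cascade on the
#' non-chloroplast stream, group comparison statistics for both streams
#' under a single non-chloroplast normalization factor, known-miRNA and
#' isomiR profiling, transgene profiling, novel-miRNA discovery on the
#' unassigned remainder, and degradome cleavage calling.  All result
#' tables are written as TSV into `config$outputDir` together with a
#' machine-readable manifest (seed, parameters, file checksums); re-running
#' with the same configuration reproduces the files byte for byte.
#'
#' @param config a [pipelineConfig()] list.
#' @param bundle optional pre-built [ReferenceBundle]; by default one is
#'   generated from `config$seed`.
#' @return (invisibly) a list with every intermediate result: `bundle`,
#'   `profiles`, `preprocess`, `partition`, `factor`, `groupStats`,
#'   `cascade`, `knownMirna`, `isomir`, `transgene`, `novel`, `degradome`,
#'   `files`.
#' @export
runPipeline <- function(config = pipelineConfig(), bundle = NULL) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(bundle)) bundle <- generateReferenceBundle(seed = config$seed)

  ## --- input reads ----------------------------------------------------
  if (is.null(config$fastq)) {
    profiles <- defaultGroupProfiles(bundle, totalReads = config$totalReads,
                                     seed = config$seed)
    libs <- lapply(profiles, function(p) generateReadLibrary(bundle, p))
    rawReads <- lapply(libs, `[[`, "reads")
  } else {
    for (f in config$fastq) {
      if (!file.exists(f)) stop("input FASTQ not found: ", f)
    }
    profiles <- NULL
    libs <- NULL
    rawReads <- lapply(config$fastq, readReadsFastq)
  }

  ## --- preprocess ------------------------------------------------------
  prep <- preprocessReads(rawReads, config$adapter3,
                          thresholds = config$thresholds,
                          minMatch = config$minMatch,
                          maxMismatch = config$maxMismatch,
                          searchStart = config$searchStart)
  files <- character(0)
  for (g in names(prep$sizeDistribution)) {
    f <- file.path(config$outputDir, sprintf("size_distribution_%s.tsv", g))
    writeTsv(prep$sizeDistribution[[g]], f)
    files[sprintf("size_%s", g)] <- f
  }

  ## --- chloroplast partition and normalization -------------------------
  part <- partitionChloroplast(prep$reads, bundle@chloroplast)
  ncCounts <- readCounts(part$nonChloroplast)
  fac <- normalizationFactor(sum(ncCounts[, 1L]), sum(ncCounts[, 2L]))

  groupStats <- list()
  for (stream in c("non_chloroplast", "chloroplast")) {
    urs <- if (stream == "chloroplast") part$chloroplast else
      part$nonChloroplast
    st <- summarizeGroups(urs, config$thresholds, factor = fac,
                          log2Threshold = config$log2Threshold)
    st <- cbind(stream = stream, st)
    groupStats[[stream]] <- st
  }
  groupStats <- do.call(rbind, groupStats)
  files["group_statistics"] <- writeTsv(
    groupStats, file.path(config$outputDir, "group_statistics.tsv"))

  ## --- classification cascade (non-chloroplast stream included; the
  ##     chloroplast stage re-derives the partition for the accounting) ---
  casc <- runCascade(prep$reads, bundle)
  files["cascade_summary"] <- writeTsv(
    stageSummary(casc), file.path(config$outputDir, "cascade_summary.tsv"))

  ## --- known miRNA profile with normalized counts ----------------------
  mir <- profileKnownMirnas(part$nonChloroplast, bundle@matureMirna)
  groups <- colnames(readCounts(prep$reads))
  mirTab <- diffexpTable(
    data.frame(feature = mir$table$mirna, sequence = mir$table$sequence,
               countA = mir$table[[groups[1]]],
               countB = mir$table[[groups[2]]]),
    fac, config$log2Threshold)
  files["known_mirna"] <- writeTsv(
    transform(mirTab, log2 = ifelse(is.na(log2), "#NUM!", log2)),
    file.path(config$outputDir, "known_mirna.tsv"))

  ## --- isomiRs ----------------------------------------------------------
  iso <- detectIsomirs(part$nonChloroplast, bundle@precursorMirna,
                       bundle@matureMap, bundle@matureMirna)
  files["isomir"] <- writeTsv(iso$table,
                              file.path(config$outputDir, "isomir.tsv"))

  ## --- transgene profile ------------------------------------------------
  tg <- profileTransgene(part$nonChloroplast,
                         c(bundle@transgene, bundle@downstream))
  files["transgene"] <- writeTsv(tg$hits,
                                 file.path(config$outputDir, "transgene.tsv"))

  ## --- novel miRNA discovery -------------------------------------------
  unas <- part$nonChloroplast[
    readSequences(part$nonChloroplast) %in% unassignedReads(casc), ]
  novel <- discoverNovelMirnas(unas, bundle,
                               mfeThreshold = config$mfeThreshold)
  novelTab <- data.frame()
  if (nrow(novel)) {
    cnt <- readCounts(unas)
    idx <- match(novel$sequence, readSequences(unas))
    novelTab <- diffexpTable(
      data.frame(feature = sprintf("candidate%02d", seq_len(nrow(novel))),
                 sequence = novel$sequence,
                 countA = cnt[idx, 1L], countB = cnt[idx, 2L]),
      fac, config$log2Threshold)
    novelTab$mfe <- novel$mfe
    novelTab$location <- novel$contig
    novelTab$verdict <- novel$verdict
    files["novel_candidates"] <- writeTsv(
      transform(novelTab, log2 = ifelse(is.na(log2), "#NUM!", log2)),
      file.path(config$outputDir, "novel_candidates.tsv"))
  }

  ## --- degradome --------------------------------------------------------
  degradome <- NULL
  if (is.null(config$fastq) && nrow(bundle@targetSites)) {
    tags <- generateDegradomeTags(
      bundle, alternativeFraction = config$alternativeFraction,
      seed = config$seed + 99L)
    novelMir <- setNames(
      bundle@features$insert[bundle@features$class == "novel"],
      bundle@features$feature[bundle@features$class == "novel"])
    calls <- degradomeCalls(tags, novelMir)
    hits <- assignTags(tags$tag, bundle@targetTranscripts)
    degSummary <- summarizeDegradome(calls, novelMir, hits$hits)
    files["degradome"] <- writeTsv(
      degSummary, file.path(config$outputDir, "degradome.tsv"))
    degradome <- list(tags = tags, calls = calls, hits = hits,
                      summary = degSummary)
  }

  ## --- manifest ---------------------------------------------------------
  yaml::write_yaml(config[setdiff(names(config), "fastq")],
                   file.path(config$outputDir, "config.yaml"))
  manifest <- list(
    package = "sRNAcascade",
    version = as.character(utils::packageVersion("sRNAcascade")),
    seed = config$seed,
    groups = groups,
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(bundle = bundle, profiles = profiles, libraries = libs,
                 preprocess = prep, partition = part, factor = fac,
                 groupStats = groupStats, cascade = casc, knownMirna = mirTab,
                 isomir = iso, transgene = tg, novel = novelTab,
                 novelCandidates = novel, degradome = degradome,
                 files = files))
}
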