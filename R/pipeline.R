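#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: the synthetic-cohort
#' configuration (or paths to user data), calling parameters, differential
#' and integration cutoffs, and the master seed. Can also be loaded from a
#' YAML file whose keys mirror the argument names.
#'
#' @param outDir output directory (created if needed).
#' @param seed master seed; all stage substreams derive from it.
#' @param cohort a [cohortConfig()].
#' @param nChrom,chromLength,spacing toy-genome geometry for the simulate
#'   stage.
#' @param probesPerWindow,gainCut,lossCut calling parameters.
#' @param calibrate logical; calibrate thresholds on a simulated self-self
#'   control instead of using `gainCut`/`lossCut`.
#' @param targetFprGain,targetFprLoss calibration targets.
#' @param alpha significance cutoff for differential windows.
#' @param gainThreshold,lossThreshold integration concordance cutoffs.
#' @param nBackgroundGenes,nCoupledGenes,noiseSdExpr expression-stage
#'   settings.
#' @param probesPath,metadataPath,expressionPath,genesPath,genomePath
#'   optional paths to user-provided inputs (probe ratio TSV, sample
#'   metadata TSV, expression TSV, gene BED, genome-spec TSV). Setting
#'   `probesPath` switches the run onto user data (requires `metadataPath`
#'   and `genomePath`); the simulate stage is then skipped.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("cnvrun"), seed = 1,
                           cohort = cohortConfig(seed = seed),
                           nChrom = 8, chromLength = 8e7, spacing = 6000,
                           probesPerWindow = 10,
                           gainCut = 0.1, lossCut = -0.1,
                           calibrate = FALSE,
                           targetFprGain = 0.005, targetFprLoss = 0.007,
                           alpha = 0.05,
                           gainThreshold = 1.5, lossThreshold = 0.75,
                           nBackgroundGenes = 513, nCoupledGenes = 7,
                           noiseSdExpr = 0.3,
                           probesPath = NULL, metadataPath = NULL,
                           expressionPath = NULL, genesPath = NULL,
                           genomePath = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; a `cohort` mapping
#' is passed to [cohortConfig()].
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohortConfig, y$cohort)
  do.call(pipelineConfig, y)
}

#' Validate a pipeline configuration
#'
#' Reporting operation: returns every violated invariant as a character
#' vector; an empty result means the configuration is runnable.
#'
#' @param config a `PipelineConfig`.
#' @return character vector of violations (empty if valid).
#' @export
validateConfig <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(inherits(config, "PipelineConfig"), "not a PipelineConfig")
  chk(config$lossCut < 0, "lossCut must be negative")
  chk(config$gainCut > 0, "gainCut must be positive")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$probesPerWindow >= 1, "probesPerWindow must be >= 1")
  chk(config$gainThreshold > 1, "gainThreshold must exceed 1")
  chk(config$lossThreshold > 0 && config$lossThreshold < 1,
      "lossThreshold must be in (0, 1)")
  co <- config$cohort
  chk(co$nEarly >= 1, "cohort nEarly must be >= 1")
  chk(co$nLate >= 1, "cohort nLate must be >= 1")
  chk(co$noiseSd >= 0, "cohort noiseSd must be >= 0")
  for (p in c("probesPath", "metadataPath", "expressionPath", "genesPath",
              "genomePath"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      v <- c(v, paste0(p, " does not exist: ", config[[p]]))
  if (!is.null(config$probesPath)) {
    if (is.null(config$metadataPath))
      v <- c(v, "probesPath requires metadataPath")
    if (is.null(config$genomePath))
      v <- c(v, "probesPath requires genomePath")
  }
  v
}

#' Run the full pipeline
#'
#' simulate -> call -> metrics -> diff -> integrate, writing every stage
#' output as a plain file (probe TSV, metadata TSV, truth/gene BED,
#' expression TSV, SEG calls, metrics TSV, window tests TSV, regions BED,
#' integration TSV) plus a JSON manifest with the config, per-stage
#' counters, wall-clock and MD5 checksums. Re-running with the same
#' configuration reproduces identical checksums.
#'
#' @param config a [pipelineConfig()]; validation failures abort before
#'   any stage runs.
#' @return the manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  manifest <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(Sys.time() - tic, units = "secs"), 3))
    res
  }

  ## -- simulate / load -----------------------------------------------
  sim <- if (!is.null(config$probesPath)) stage("load", {
    genome <- readGenomeSpec(config$genomePath)
    cgh <- attachMetadata(readProbeTable(config$probesPath),
                          readMetadata(config$metadataPath))
    expr <- if (!is.null(config$expressionPath))
      readExpression(config$expressionPath) else NULL
    genes <- if (!is.null(config$genesPath))
      readGeneBed(config$genesPath) else NULL
    if (!is.null(expr))
      checkSampleConsistency(cgh, readMetadata(config$metadataPath), expr)
    list(genome = genome, probes = probeRanges(cgh), cgh = cgh,
         truth = NULL, events = NULL, genes = genes, expr = expr)
  }) else stage("simulate", {
    s <- simulateStudy(seed = config$seed, config = config$cohort,
                       nChrom = config$nChrom,
                       chromLength = config$chromLength,
                       spacing = config$spacing,
                       nBackgroundGenes = config$nBackgroundGenes,
                       nCoupledGenes = config$nCoupledGenes,
                       noiseSdExpr = config$noiseSdExpr)
    writeProbeTable(s$cgh, out("probes.tsv"))
    writeMetadata(as.data.frame(colData(s$cgh)), out("metadata.tsv"))
    truthNamed <- s$truth
    if (length(truthNamed))
      mcols(truthNamed)$gene_id <- sprintf("%s:%s:%s",
        mcols(truthNamed)$sample_id, mcols(truthNamed)$direction,
        fmtNum(mcols(truthNamed)$magnitude))
    writeGeneBed(truthNamed, out("truth.bed"))
    writeGeneBed(s$genes, out("genes.bed"))
    writeExpression(s$expr, out("expression.tsv"))
    s
  })

  ## -- call ----------------------------------------------------------
  calls <- stage("call", {
    control <- if (config$calibrate)
      simulateControlPair(sim$probes, config$cohort$noiseSd,
                          kind = "self_self",
                          seed = childSeed(config$seed, 21)) else NULL
    cl <- callCopyNumber(sim$cgh, sim$genome,
                         probesPerWindow = config$probesPerWindow,
                         thresholds = cnThresholds(config$gainCut,
                                                   config$lossCut),
                         control = control,
                         targetFprGain = config$targetFprGain,
                         targetFprLoss = config$targetFprLoss)
    writeSeg(segTable(cl), out("calls.seg"))
    cl
  })
  manifest$stages$call$windows <- nrow(calls)
  manifest$stages$call$windows_masked <-
    sum(mcols(windowRanges(calls))$masked)
  manifest$thresholds <- thresholdsOf(calls)[c("gainCut", "lossCut")]

  ## -- metrics -------------------------------------------------------
  metrics <- stage("metrics", {
    m <- sampleMetrics(calls)
    write.table(cbind(m[1:4], lapply(m[5:6], fmtNum)), out("metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })
  manifest$stages$metrics$group_p <- tryCatch(
    as.list(round(compareGroupCounts(metrics), 6)),
    error = function(e) NULL, warning = function(w) NULL)

  ## -- diff ----------------------------------------------------------
  regions <- stage("diff", {
    tests <- testAllWindows(calls)
    tw <- tests
    tw$p <- fmtNum(tw$p)
    write.table(tw, out("windows.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    reg <- mergeRegions(tests, calls, alpha = config$alpha)
    reg <- annotateSro(reg, calls)
    writeRegionsBed(reg, out("regions.bed"))
    reg
  })
  manifest$stages$diff$regions <- length(regions)
  manifest$stages$diff$significant_genome_pct <-
    round(significantGenomeFraction(regions, sim$genome), 4)

  ## -- integrate -----------------------------------------------------
  integration <- if (is.null(sim$expr) || is.null(sim$genes)) NULL
  else stage("integrate", {
    notes <- character(0)
    rec <- withCallingHandlers(
      integrateExpression(calls, sim$expr, sim$genes, regions,
                          gainThreshold = config$gainThreshold,
                          lossThreshold = config$lossThreshold,
                          alpha = config$alpha),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (length(notes))
      manifest$stages$integrate_notes <- unique(notes)
    recOut <- rec
    for (cl in c("ratio_gain", "ratio_loss", "group_p"))
      recOut[[cl]] <- fmtNum(recOut[[cl]])
    write.table(recOut, out("integration.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rec
  })
  if (!is.null(integration)) {
    manifest$stages$integrate$genes <- nrow(integration)
    manifest$stages$integrate$shortlisted <- sum(integration$shortlisted)
  }

  files <- c("probes.tsv", "metadata.tsv", "truth.bed", "genes.bed",
             "expression.tsv", "calls.seg", "metrics.tsv", "windows.tsv",
             "regions.bed", "integration.tsv")
  files <- files[file.exists(vapply(files, out, ""))]
  manifest$checksums <- as.list(tools::md5sum(vapply(files, out, "")))
  names(manifest$checksums) <- files
  manifest$total_seconds <- round(as.numeric(Sys.time() - t0,
                                             units = "secs"), 3)
  cfgForHash <- config
  cfgForHash$outDir <- NULL
  cfgForHash$cohort <- unclass(cfgForHash$cohort)
  cfgTmp <- tempfile()
  writeLines(jsonlite::toJSON(unclass(cfgForHash), auto_unbox = TRUE,
                              digits = NA, null = "null"), cfgTmp)
  manifest$config_md5 <- unname(tools::md5sum(cfgTmp))
  unlink(cfgTmp)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
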