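#' @include topology.R junction.R io.R
NULL

.scenarioFromList <- function(x, seed = 1L) {
  if (!is.null(x$preset)) return(scenarioPreset(x$preset, seed = seed))
  ScenarioSpec(
    copiesPerAllele = if (is.null(x$copiesPerAllele)) c(1L, 1L)
                      else unlist(x$copiesPerAllele),
    episomeCount = if (is.null(x$episomeCount)) 0 else x$episomeCount,
    aneuploidy = if (is.null(x$aneuploidy)) numeric()
                 else unlist(x$aneuploidy),
    rdnaFactor = if (is.null(x$rdnaFactor)) 1 else x$rdnaFactor,
    seed = seed)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON with optional blocks \code{model} (arguments of
#' [buildLocusModel()]), \code{scenario} and \code{reference} (either a
#' \code{preset} name or explicit \linkS4class{ScenarioSpec} fields),
#' \code{params} (pipeline parameters) and \code{seed}. Every parameter has
#' a default matching the study conditions (500 bp windows, 10 kb smoothing
#' span, 90 bp reads, depth 44) or a declared package default.
#'
#' @param path config file path (.yaml/.yml or .json).
#' @return a named list understood by [runPipeline()].
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' Run the full eccDNA / tandem-amplification inference pipeline
#'
#' Orchestrates the whole chain on synthetic data: build the sample and
#' reference genomes from their scenarios, simulate paired-end reads,
#' compute depth tracks and the smoothed log2 ratio, call CNV segments,
#' detect and cross-match soft-clip breakpoints into junction calls,
#' annotate breakpoint microhomologies, run the in-silico PCR and digest
#' assays, and classify the locus topology. Identical configuration and
#' seed give an identical report.
#'
#' @param model a \linkS4class{LocusModel} (built with defaults when NULL).
#' @param scenario sample \linkS4class{ScenarioSpec} (or preset name).
#' @param reference reference \linkS4class{ScenarioSpec}; default parent.
#' @param depth,readLen,fragMean,fragSd,errRate read-simulation parameters
#'   (defaults: 44x coverage, 90 bp reads, 500 bp fragments).
#' @param window,span,threshold,minWindows CNV parameters (500 bp windows,
#'   10 kb smoothing, |log2| >= 0.4 over >= 5 windows).
#' @param minClip,tol,minSupport junction-detection parameters.
#' @param seed master seed; read simulation derives one sub-seed per
#'   sample.
#' @param outDir when non-NULL, stage artifacts are written there as plain
#'   files (FASTA/FASTQ/SAM/bedGraph/TSV/JSON) so stages can be re-run
#'   independently.
#' @param config optional path to a [readRunConfig()] file; explicit
#'   arguments override it.
#' @return (invisibly) the run report: a nested list with elements
#'   \code{parameters}, \code{segments}, \code{junctions},
#'   \code{topology}, and per-sample read statistics. Written to
#'   \code{report.json} under \code{outDir} when artifacts are enabled.
#' @examples
#' \donttest{
#' model <- buildLocusModel(chromLength = 40000, unitLength = 3000,
#'                          boundaryFragment = 2000, hindToEnd = 1200,
#'                          outsideFragment = 5000, p3Product = 4500,
#'                          auxChromLength = 0, rdnaChromLength = 0)
#' rep <- runPipeline(model, scenario = "episome", depth = 30, seed = 1)
#' rep$topology$verdict
#' }
#' @export
runPipeline <- function(model = NULL, scenario = "tandem_both",
                        reference = "parent",
                        depth = 44, readLen = 90L, fragMean = 500,
                        fragSd = 50, errRate = 0.002,
                        window = 500L, span = 10000, threshold = 0.4,
                        minWindows = 5L, minClip = 10L, tol = 5L,
                        minSupport = 3L, seed = 1L, outDir = NULL,
                        config = NULL) {
  supplied <- names(match.call())[-1]
  if (!is.null(config)) {
    cfg <- if (is.character(config)) readRunConfig(config) else config
    if (!is.null(cfg$seed) && !("seed" %in% supplied)) seed <- cfg$seed
    if (!is.null(cfg$model) && is.null(model))
      model <- do.call(buildLocusModel, c(cfg$model, list(seed = seed)))
    if (!is.null(cfg$scenario) && !("scenario" %in% supplied))
      scenario <- .scenarioFromList(cfg$scenario, seed = seed)
    if (!is.null(cfg$reference) && !("reference" %in% supplied))
      reference <- .scenarioFromList(cfg$reference, seed = seed)
    for (p in names(cfg$params))
      if (p %in% names(formals(runPipeline)) && !(p %in% supplied))
        assign(p, cfg$params[[p]])
  }
  if (is.null(model)) model <- buildLocusModel(seed = seed)
  if (is.character(scenario)) scenario <- scenarioPreset(scenario, seed = seed)
  if (is.character(reference))
    reference <- scenarioPreset(reference, seed = seed)
  writeOut <- !is.null(outDir)
  if (writeOut) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  note <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

  ## stage: simulate ----------------------------------------------------------
  note("simulate", "building genomes and simulating reads at %gx", depth)
  sampleBuild <- applyScenario(model, scenario)
  refBuild <- applyScenario(model, reference)
  simS <- simulateReads(sampleBuild, depth = depth, readLen = readLen,
                        fragMean = fragMean, fragSd = fragSd,
                        errRate = errRate,
                        seed = .childSeed(seed, "sample"), sample = "sample")
  simR <- simulateReads(refBuild, depth = depth, readLen = readLen,
                        fragMean = fragMean, fragSd = fragSd,
                        errRate = errRate,
                        seed = .childSeed(seed, "reference"),
                        sample = "reference")
  if (writeOut) {
    writeParentFasta(model, file.path(outDir, "parent.fasta"))
    writeFeatureBed(model, file.path(outDir, "features.bed"))
    writeTruthJson(sampleBuild, file.path(outDir, "truth_sample.json"))
    writeSimFastq(simS, outDir); writeSimFastq(simR, outDir)
    writeSimSam(simS, model, file.path(outDir, "sample.sam"))
    writeSimSam(simR, model, file.path(outDir, "reference.sam"))
  }

  ## stage: depth / ratio / segments ------------------------------------------
  note("depth", "windowed depth (%d bp) and log2 ratio (span %g bp)",
       window, span)
  trackS <- computeDepthTrack(simS$alignments, model, window = window)
  trackR <- computeDepthTrack(simR$alignments, model, window = window)
  ratio <- smoothTrack(log2Ratio(trackS, trackR), span = span)
  segments <- callSegments(ratio, threshold = threshold,
                           minWindows = minWindows)
  segDf <- as.data.frame(segments)
  if (writeOut) {
    writeBedGraph(ratio, file.path(outDir, "log2_raw.bedGraph"), "log2")
    writeBedGraph(ratio, file.path(outDir, "log2_smoothed.bedGraph"),
                  "smoothed")
    write.table(segDf, file.path(outDir, "segments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## stage: junction ----------------------------------------------------------
  note("junction", "collecting soft-clips (min clip %d)", minClip)
  clips <- collectClipped(simS$alignments, minClip = minClip)
  clusters <- clusterBreakpoints(clips, tol = tol, minSupport = minSupport)
  jx <- if (nrow(clusters) >= 2L) crossMatch(clusters, model, minClip = minClip)
        else list(calls = list(), unresolved = clusters)
  jx$calls <- lapply(jx$calls, annotateJunction, model = model)
  if (nrow(jx$unresolved))
    note("junction", "%d unresolved breakpoint cluster(s)",
         nrow(jx$unresolved))
  if (writeOut && length(jx$calls))
    writeJunctionBedpe(jx$calls[[1]], file.path(outDir, "junction.bedpe"))

  ## stage: validate / classify -----------------------------------------------
  note("classify", "in-silico assays and topology classification")
  evidence <- gatherAssayEvidence(sampleBuild)
  unitGain <- segDf[segDf$seqnames == model@unitChrom &
                    segDf$direction == "gain" &
                    segDf$start - 1L < model@unitEnd &
                    segDf$end > model@unitStart, , drop = FALSE]
  coverageFold <- if (nrow(unitGain)) unitGain$fold[1] else 1
  topology <- classifyTopology(evidence, coverageFold = coverageFold)

  report <- list(
    schemaVersion = "1.0",
    seed = as.integer(seed),
    parameters = list(depth = depth, readLen = readLen, window = window,
                      span = span, threshold = threshold,
                      minWindows = minWindows, minClip = minClip, tol = tol,
                      minSupport = minSupport),
    samples = list(
      sample = list(reads = nrow(simS$alignments),
                    alignedBases = trackS@totalBases),
      reference = list(reads = nrow(simR$alignments),
                       alignedBases = trackR@totalBases)),
    segments = lapply(seq_len(nrow(segDf)), function(i) list(
      chrom = as.character(segDf$seqnames[i]), start = segDf$start[i] - 1L,
      end = segDf$end[i], direction = segDf$direction[i],
      fold = segDf$fold[i], foldRounded = segDf$foldRounded[i],
      meanSmoothed = segDf$meanSmoothed[i], nWindows = segDf$nWindows[i])),
    junctions = lapply(jx$calls, function(j) list(
      chrom = j@chrom, leftBp = j@leftBp, rightBp = j@rightBp,
      unitLength = unitLength(j), ambiguitySpan = j@ambiguitySpan,
      supportLeft = j@supportLeft, supportRight = j@supportRight,
      microhomology = j@microhomology)),
    topology = list(
      verdict = topology@verdict,
      copiesPerAllele = topology@copiesPerAllele,
      copiesFromIntensity = topology@copiesFromIntensity,
      agreement = topology@agreement,
      notes = topology@notes,
      p1 = evidence$p1, p2 = evidence$p2,
      p3Short = evidence$p3Short, p3Long = evidence$p3Long,
      has11kb = evidence$has11kb, hasHighMW = evidence$hasHighMW,
      intensityRatio = evidence$intensityRatio))
  ok <- validateReport(report)
  if (!isTRUE(ok)) .stageStop("report", paste(ok, collapse = "; "))
  if (writeOut)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

## minimal JSON-schema checker (type / properties / required / items) --
## enough to validate the report layout against the shipped schema
.checkSchema <- function(obj, schema, path = "$") {
  errs <- character()
  ty <- schema$type
  okType <- switch(ty,
    object = is.list(obj) && (is.null(names(obj)) == (length(obj) == 0L)),
    array = is.list(obj) || is.vector(obj),
    string = is.character(obj),
    number = is.numeric(obj),
    integer = is.numeric(obj) && all(obj == round(obj)),
    boolean = is.logical(obj),
    TRUE)
  if (!isTRUE(okType))
    return(sprintf("%s: expected %s", path, ty))
  if (ty == "object") {
    for (req in schema$required)
      if (!req %in% names(obj))
        errs <- c(errs, sprintf("%s: missing required field '%s'", path, req))
    for (nm in names(schema$properties))
      if (nm %in% names(obj))
        errs <- c(errs, .checkSchema(obj[[nm]], schema$properties[[nm]],
                                     paste0(path, ".", nm)))
  } else if (ty == "array" && !is.null(schema$items)) {
    items <- if (is.data.frame(obj))
      lapply(seq_len(nrow(obj)), function(i) as.list(obj[i, ]))
    else obj
    for (i in seq_along(items))
      errs <- c(errs, .checkSchema(items[[i]], schema$items,
                                   sprintf("%s[%d]", path, i)))
  }
  errs
}

#' Validate a pipeline report against the shipped JSON schema
#'
#' @param report report list from [runPipeline()] (or parsed from its
#'   \code{report.json}).
#' @param schemaPath schema file; defaults to the schema shipped with the
#'   package.
#' @return TRUE, or a character vector of violations.
#' @export
validateReport <- function(report,
                           schemaPath = system.file("schema",
                                                    "report-schema.json",
                                                    package = "eccFinder")) {
  schema <- jsonlite::read_json(schemaPath)
  errs <- .checkSchema(report, schema)
  if (length(errs)) errs else TRUE
}
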