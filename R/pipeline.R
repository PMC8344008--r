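#' Pipeline configuration
#'
#' One configuration object drives the end-to-end pipeline. Exactly one
#' input source must be given: real data (\code{petTable} +
#' \code{clinicalPath}), a tabular cohort simulation (\code{cohortSim}),
#' or an imaging simulation (\code{phantomSim}) that generates a phantom
#' pair per patient and runs them through segmentation.
#'
#' @param petTable data.frame (or CSV path) with columns patient_id,
#'   timepoint, pet (NIfTI path), organs (NIfTI label path).
#' @param clinicalPath CSV with patient_id, psa, psa_best, ldh, os_months,
#'   event.
#' @param cohortSim a [CohortSimSpec-class].
#' @param phantomSim list with \code{nPatients} (and optionally
#'   \code{noiseSd}, \code{psfFwhmMm}).
#' @param minVoxels,overlapFrac,sdConvention segmentation options.
#' @param tvDeclineThreshold,psaDeclineThreshold,expressionCutoff response
#'   boundaries (defaults 30, 50, 14.3).
#' @param alpha significance level for the analysis report.
#' @param seed root seed; all pipeline randomness derives from it.
#' @param outDir output directory.
#' @return list of class \code{pipelineConfig}.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(petTable = NULL, clinicalPath = NULL,
                           cohortSim = NULL, phantomSim = NULL,
                           minVoxels = 1L, overlapFrac = 0.5,
                           sdConvention = "population",
                           tvDeclineThreshold = 30,
                           psaDeclineThreshold = 50,
                           expressionCutoff = 14.3, alpha = 0.05,
                           seed = 1L, outDir = tempfile("psmavol")) {
  sources <- c(real = !is.null(petTable) || !is.null(clinicalPath),
               cohort = !is.null(cohortSim),
               phantom = !is.null(phantomSim))
  if (sum(sources) != 1L)
    stop("exactly one of real-data paths, cohortSim or phantomSim ",
         "must be provided")
  if (sources[["real"]] && (is.null(petTable) || is.null(clinicalPath)))
    stop("real-data mode needs both petTable and clinicalPath")
  if (any(c(tvDeclineThreshold, psaDeclineThreshold,
            expressionCutoff) <= 0))
    stop("response thresholds must be positive")
  structure(list(petTable = petTable, clinicalPath = clinicalPath,
                 cohortSim = cohortSim, phantomSim = phantomSim,
                 minVoxels = minVoxels, overlapFrac = overlapFrac,
                 sdConvention = sdConvention,
                 tvDeclineThreshold = tvDeclineThreshold,
                 psaDeclineThreshold = psaDeclineThreshold,
                 expressionCutoff = expressionCutoff, alpha = alpha,
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; keys mirror the [pipelineConfig()] arguments
#'   (\code{cohortSim} and \code{phantomSim} as key-value maps).
#' @param ... overrides applied after reading.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path, ...) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(cfg$cohortSim))
    cfg$cohortSim <- do.call(cohortSimSpec, cfg$cohortSim)
  if (!is.null(cfg$petTable) && is.character(cfg$petTable))
    cfg$petTable <- utils::read.csv(cfg$petTable)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipelineConfig, cfg)
}

# Segment one scan and return its per-lesion table plus metrics row.
segmentToRows <- function(volume, masks, config, patientId) {
  seg <- segmentScan(volume, masks, minVoxels = config$minVoxels,
                     overlapFrac = config$overlapFrac,
                     sdConvention = config$sdConvention)
  metrics <- aggregateScan(seg$lesions, scanId = scanId(volume),
                           timepoint = timepoint(volume))
  list(lesions = lesionTable(seg$lesions, scanId(volume),
                             timepoint(volume)),
       metrics = scanMetricsRow(metrics, patientId))
}

# Imaging-simulation branch: a phantom pair per patient. The interim
# phantom shrinks each lesion isotropically by a per-patient factor so
# roughly half the simulated patients are volumetric responders.
simulateImagingCohort <- function(config) {
  nP <- config$phantomSim$nPatients
  noiseSd <- config$phantomSim$noiseSd %||% 0.05
  psf <- config$phantomSim$psfFwhmMm %||% 4
  lesionRows <- list()
  metricRows <- list()
  withSeed(config$seed, {
    for (p in seq_len(nP)) {
      f <- stats::runif(1, 0.25, 1.25)      # interim/baseline volume ratio
      baseSpec <- defaultPhantomSpec(seed = config$seed + 2L * p,
                                     psfFwhmMm = psf, noiseSd = noiseSd)
      lesions <- baseSpec@lesions
      intLesions <- lesions
      intLesions$radius <- lesions$radius * f^(1 / 3)
      intSpec <- defaultPhantomSpec(seed = config$seed + 2L * p + 1L,
                                    psfFwhmMm = psf, noiseSd = noiseSd,
                                    lesions = intLesions)
      for (tp in c("baseline", "interim")) {
        ph <- generatePhantom(if (tp == "baseline") baseSpec else intSpec)
        vol <- petVolume(suvValues(ph@volume), voxelSpacing(ph@volume),
                         scanId = sprintf("P%03d_%s", p, tp),
                         timepoint = tp)
        res <- segmentToRows(vol, ph@organMasks, config,
                             sprintf("P%03d", p))
        lesionRows[[length(lesionRows) + 1L]] <- res$lesions
        metricRows[[length(metricRows) + 1L]] <- res$metrics
      }
    }
    psa <- stats::rlnorm(nP, log(146), 1.2)
    clinical <- data.frame(
      patient_id = sprintf("P%03d", seq_len(nP)),
      psa = psa, psa_best = psa * stats::rlnorm(nP, log(0.6), 0.9),
      ldh = stats::rlnorm(nP, log(282), 0.5),
      os_months = stats::rexp(nP, log(2) / 15),
      event = stats::runif(nP) < 0.6, stringsAsFactors = FALSE)
    list(lesions = do.call(rbind, lesionRows),
         scans = do.call(rbind, metricRows), clinical = clinical)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end pipeline
#'
#' simulate-or-load, segment baseline and interim scans, aggregate
#' metrics, classify response, run the outcome analysis, and write a
#' manifest recording the configuration, seed, package version and
#' per-stage row counts. Deterministic for a fixed seed. The analysis
#' stage requires at least two events and four patients; below that it is
#' skipped and the manifest says so.
#'
#' @param config a [pipelineConfig()].
#' @return the report directory path, invisibly.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(cohortSim = cohortSimSpec(seed = 9),
#'                       outDir = tempfile())
#' runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$cohortSim)) {
      stage <- "simulate"
      cohort <- simulateCohort(config$cohortSim)
      counts$patients <- nrow(cohort)
      utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                       row.names = FALSE)
      response <- cohort
    } else {
      if (!is.null(config$phantomSim)) {
        stage <- "simulate"
        sim <- simulateImagingCohort(config)
        lesions <- sim$lesions
        scans <- sim$scans
        clinical <- sim$clinical
      } else {
        stage <- "load"
        pt <- config$petTable
        if (is.character(pt)) pt <- utils::read.csv(pt)
        clinical <- utils::read.csv(config$clinicalPath)
        stage <- "segment"
        lesionRows <- list()
        metricRows <- list()
        for (r in seq_len(nrow(pt))) {
          vol <- readPetVolume(pt$pet[r], scanId = basename(pt$pet[r]),
                               timepoint = pt$timepoint[r])
          masks <- readOrganMasks(pt$organs[r],
                                  labelMap = c(liver = 1L, spleen = 2L,
                                               kidney_left = 3L,
                                               kidney_right = 4L))
          res <- segmentToRows(vol, masks, config, pt$patient_id[r])
          lesionRows[[r]] <- res$lesions
          metricRows[[r]] <- res$metrics
        }
        lesions <- do.call(rbind, lesionRows)
        scans <- do.call(rbind, metricRows)
      }
      counts$scans <- nrow(scans)
      counts$lesions <- nrow(lesions)
      utils::write.csv(lesions, file.path(outDir, "lesions.csv"),
                       row.names = FALSE)
      utils::write.csv(scans, file.path(outDir, "scan_metrics.csv"),
                       row.names = FALSE)
      stage <- "response"
      response <- buildResponseTable(scans, clinical,
                                     config$tvDeclineThreshold,
                                     config$psaDeclineThreshold,
                                     config$expressionCutoff)
      counts$patients <- nrow(response)
      utils::write.csv(response, file.path(outDir, "response.csv"),
                       row.names = FALSE)
    }
    stage <- "analysis"
    analysisNote <- "ok"
    if (nrow(response) >= 4L && sum(response$event) >= 2L) {
      runOutcomeAnalysis(response, outDir = outDir, alpha = config$alpha,
                         expressionCutoff = config$expressionCutoff)
    } else {
      analysisNote <- "skipped: too few patients or events"
    }
    analysisNote
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "psmavol",
    version = as.character(utils::packageVersion("psmavol")),
    seed = config$seed,
    config = configAsList(config),
    stage_counts = counts,
    analysis = result)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outDir)
}

# Serializable view of the config (S4 specs flattened to lists).
configAsList <- function(config) {
  out <- unclass(config)
  if (!is.null(out$cohortSim)) {
    cs <- out$cohortSim
    out$cohortSim <- list(nPatients = cs@nPatients, betaLogTv = cs@betaLogTv,
                          betaResponse = cs@betaResponse,
                          fracLowExpression = cs@fracLowExpression,
                          tvMedianMl = cs@tvMedianMl, tvIqrMl = cs@tvIqrMl,
                          censoringRate = cs@censoringRate, seed = cs@seed)
  }
  if (is.data.frame(out$petTable)) out$petTable <- "inline data.frame"
  out
}
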