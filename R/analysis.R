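# The full outcome-analysis plan over a per-patient cohort table.

coxOrNull <- function(...) {
  tryCatch(coxFit(...), error = function(e)
    structure(list(error = conditionMessage(e)), class = "coxFitError"))
}

coxRows <- function(fit, model, cohortLabel) {
  if (inherits(fit, "coxFitError") || is.null(fit))
    return(data.frame(model = model, cohort = cohortLabel,
                      covariate = NA_character_, hr = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      wald_p = NA_real_, lrt_p = NA_real_, n = NA_integer_,
                      note = if (is.null(fit)) "not run" else fit$error,
                      stringsAsFactors = FALSE))
  data.frame(model = model, cohort = cohortLabel,
             covariate = fit$table$covariate, hr = fit$table$hr,
             ci_lower = fit$table$ciLower, ci_upper = fit$table$ciUpper,
             wald_p = fit$table$waldP, lrt_p = fit$lrtP, n = fit$nUsed,
             note = "", stringsAsFactors = FALSE)
}

kmCurveRows <- function(km, model) {
  f <- km$fit
  data.frame(model = model,
             group = rep(sub("^group=", "", names(f$strata)),
                         times = f$strata),
             time = f$time, surv = f$surv, n_risk = f$n.risk,
             n_event = f$n.event, stringsAsFactors = FALSE)
}

plotKm <- function(km, title, path) {
  grDevices::png(path, width = 720, height = 560)
  on.exit(grDevices::dev.off())
  graphics::plot(km$fit, col = c("#1f78b4", "#e6a100"), lwd = 2,
                 xlab = "Months", ylab = "Overall survival", main = title,
                 mark.time = TRUE)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("#1f78b4", "#e6a100"),
                   legend = sprintf("%s (median %s mo)",
                                    names(km$medians),
                                    format(km$medians, digits = 3)))
  graphics::mtext(sprintf("log-rank p = %s | HR = %s",
                          format.pval(km$logrankP, digits = 3),
                          format(km$hr, digits = 3)), side = 3, cex = 0.9)
}

#' Run the full outcome analysis on a cohort
#'
#' Executes the complete statistical plan on a per-patient table:
#' univariable Cox regressions of the log-transformed baseline and interim
#' PET metrics (PSMA-TV, TLQ, meanSUVmax); multivariable models of each
#' baseline PET metric adjusted for log PSA and log LDH; Cox models of
#' volumetric response (the log baseline/interim ratio and the binary
#' >30 percent-decline flag), each fitted in the full cohort and in the
#' subgroup excluding low-PSMA-expression patients - the contrast of
#' interest, since a spurious volume decline in low-expression disease
#' masks the prognostic value of true response; Kaplan-Meier median-split
#' comparisons; maximally-selected-rank-statistic cutoffs for baseline
#' meanSUVmax and TLQ; Martingale residual diagnostics; and the
#' volumetric-vs-biochemical response comparison.
#'
#' @param cohort per-patient data.frame (see [simulateCohort()] or
#'   [buildResponseTable()] for the expected columns).
#' @param outDir optional directory; when given, writes cox_results.csv,
#'   km_curves.csv, cutoffs.csv, martingale.csv, report.json and KM plots.
#' @param alpha significance level recorded in the report.
#' @param expressionCutoff low-expression boundary (default 14.3).
#' @param maxstatMinProp minimum group proportion for cutoff search.
#' @return list of class \code{outcomeReport}: \code{coxTable} (all
#'   models), \code{km} (named list of [kmLogrank()] results),
#'   \code{cutoffs}, \code{martingale}, \code{responseComparison},
#'   \code{headline} (full-cohort vs subgroup HRs of the continuous log
#'   TV-ratio response model), \code{n}.
#' @examples
#' rep <- runOutcomeAnalysis(simulateCohort(cohortSimSpec(seed = 5)))
#' rep$headline
#' @export
runOutcomeAnalysis <- function(cohort, outDir = NULL, alpha = 0.05,
                               expressionCutoff = 14.3,
                               maxstatMinProp = 0.1) {
  if (!"low_expression" %in% names(cohort))
    cohort$low_expression <- !(cohort$mean_suv_max_baseline >
                                 expressionCutoff)
  sub <- cohort[!cohort$low_expression, , drop = FALSE]

  uniCovs <- c("psma_tv_baseline", "psma_tv_interim", "tlq_baseline",
               "tlq_interim", "mean_suv_max_baseline",
               "mean_suv_max_interim")
  uniCovs <- intersect(uniCovs, names(cohort))
  rows <- list()
  for (cv in uniCovs)
    rows[[length(rows) + 1L]] <-
      coxRows(coxOrNull(cohort, cv), paste0("uni_", cv), "full")
  for (cv in intersect(c("psma_tv_baseline", "tlq_baseline",
                         "mean_suv_max_baseline"), names(cohort)))
    rows[[length(rows) + 1L]] <-
      coxRows(coxOrNull(cohort, c(cv, "psa", "ldh")),
              paste0("multi_", cv), "full")

  # volumetric response: log ratio (continuous) and binary flag,
  # full cohort vs excluding low expression
  fitRatioFull <- coxOrNull(cohort, "tv_ratio")
  fitRatioSub <- coxOrNull(sub, "tv_ratio")
  fitFlagFull <- coxOrNull(cohort, "tv_responder")
  fitFlagSub <- coxOrNull(sub, "tv_responder")
  rows[[length(rows) + 1L]] <- coxRows(fitRatioFull, "uni_tv_ratio", "full")
  rows[[length(rows) + 1L]] <- coxRows(fitRatioSub, "uni_tv_ratio",
                                       "no_low_expression")
  rows[[length(rows) + 1L]] <- coxRows(fitFlagFull, "uni_tv_responder",
                                       "full")
  rows[[length(rows) + 1L]] <- coxRows(fitFlagSub, "uni_tv_responder",
                                       "no_low_expression")
  rows[[length(rows) + 1L]] <-
    coxRows(coxOrNull(cohort, c("tv_ratio", "psa", "ldh")),
            "multi_tv_ratio", "full")
  rows[[length(rows) + 1L]] <-
    coxRows(coxOrNull(sub, c("tv_ratio", "psa", "ldh")),
            "multi_tv_ratio", "no_low_expression")
  coxTable <- do.call(rbind, rows)

  km <- list()
  for (cv in intersect(c("psma_tv_baseline", "tlq_baseline",
                         "mean_suv_max_baseline"), names(cohort))) {
    km[[paste0("median_", cv)]] <- tryCatch({
      hi <- medianBinarize(cohort, cv)
      kmLogrank(cohort, factor(ifelse(hi, "high", "low"),
                               levels = c("low", "high")))
    }, error = function(e) NULL)
  }
  km$tv_responder <- tryCatch(
    kmLogrank(cohort, factor(ifelse(cohort$tv_responder, "responder",
                                    "non-responder"),
                             levels = c("non-responder", "responder"))),
    error = function(e) NULL)
  if ("psa_responder" %in% names(cohort))
    km$psa_responder <- tryCatch(
      kmLogrank(cohort, factor(ifelse(cohort$psa_responder, "responder",
                                      "non-responder"),
                               levels = c("non-responder", "responder"))),
      error = function(e) NULL)
  km <- km[!vapply(km, is.null, logical(1))]

  # cutoff finder for the expression/TLQ stratification, computed within
  # the responder subgroup when it can support a split, else full cohort
  cutoffFor <- function(cv) {
    respSub <- cohort[cohort$tv_responder %in% TRUE, , drop = FALSE]
    res <- tryCatch(maxstatCutoff(respSub, cv, maxstatMinProp),
                    error = function(e) NULL)
    scope <- "tv_responders"
    if (is.null(res)) {
      res <- tryCatch(maxstatCutoff(cohort, cv, maxstatMinProp),
                      error = function(e) NULL)
      scope <- "full"
    }
    if (is.null(res)) return(NULL)
    data.frame(covariate = cv, scope = scope, cutoff = res$cutoff,
               statistic = res$statistic, n_low = res$groupSizes[[1L]],
               n_high = res$groupSizes[[2L]], stringsAsFactors = FALSE)
  }
  cutoffs <- do.call(rbind, Filter(Negate(is.null),
    lapply(intersect(c("mean_suv_max_baseline", "tlq_baseline"),
                     names(cohort)), cutoffFor)))

  martingale <- data.frame(
    patient_id = cohort$patient_id, os_months = cohort$os_months,
    event = cohort$event,
    residual_null = martingaleResiduals(cohort),
    stringsAsFactors = FALSE)
  if (!inherits(fitRatioFull, "coxFitError"))
    martingale$residual_tv_ratio <- martingaleResiduals(cohort, fitRatioFull)

  comparison <- tryCatch(correlateAndCompare(cohort),
                         error = function(e) NULL)

  hl <- function(fit) {
    if (inherits(fit, "coxFitError")) return(rep(NA_real_, 4L))
    c(fit$table$hr[1L], fit$table$ciLower[1L], fit$table$ciUpper[1L],
      fit$table$waldP[1L])
  }
  headline <- data.frame(
    cohort = c("full", "no_low_expression"),
    rbind(hl(fitRatioFull), hl(fitRatioSub)))
  names(headline)[2:5] <- c("hr", "ci_lower", "ci_upper", "p")

  report <- structure(
    list(coxTable = coxTable, km = km, cutoffs = cutoffs,
         martingale = martingale, responseComparison = comparison,
         headline = headline, alpha = alpha, n = nrow(cohort),
         nLowExpression = sum(cohort$low_expression, na.rm = TRUE)),
    class = "outcomeReport")

  if (!is.null(outDir)) writeOutcomeReport(report, outDir)
  report
}

#' @export
print.outcomeReport <- function(x, ...) {
  cat("Outcome analysis on", x$n, "patients (",
      x$nLowExpression, "low expression )\n")
  cat("\nVolumetric-response hazard ratios (log baseline/interim ratio):\n")
  print(x$headline, digits = 3, row.names = FALSE)
  if (!is.null(x$responseComparison))
    cat("\nSpearman rho (TV vs PSA decline):",
        format(x$responseComparison$spearmanRho, digits = 3), "\n")
  invisible(x)
}

# Write the report directory: CSV tables, JSON summary, KM plots.
writeOutcomeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$coxTable,
                   file.path(outDir, "cox_results.csv"), row.names = FALSE)
  kmRows <- do.call(rbind, lapply(names(report$km), function(nm)
    kmCurveRows(report$km[[nm]], nm)))
  if (!is.null(kmRows))
    utils::write.csv(kmRows, file.path(outDir, "km_curves.csv"),
                     row.names = FALSE)
  if (!is.null(report$cutoffs))
    utils::write.csv(report$cutoffs, file.path(outDir, "cutoffs.csv"),
                     row.names = FALSE)
  utils::write.csv(report$martingale, file.path(outDir, "martingale.csv"),
                   row.names = FALSE)
  for (nm in names(report$km))
    plotKm(report$km[[nm]], nm, file.path(outDir, paste0("km_", nm, ".png")))
  summaryList <- list(
    n = report$n, n_low_expression = report$nLowExpression,
    alpha = report$alpha, headline = report$headline,
    medians = lapply(report$km, function(k) as.list(k$medians)),
    logrank_p = lapply(report$km, function(k) k$logrankP),
    response_comparison = report$responseComparison)
  jsonlite::write_json(summaryList, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}
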