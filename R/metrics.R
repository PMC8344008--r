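#' Aggregate lesion metrics to scan level
#'
#' PSMA-TV is the sum of lesion volumes (ml), the TLQ metric the sum of
#' per-lesion TLQ, and meanSUVmax the unweighted arithmetic mean of lesion
#' SUVmax (the conventional proxy for average PSMA expression; it is not
#' volume-weighted). An empty lesion list yields zero volumes and a
#' missing meanSUVmax.
#'
#' @param lesions list of [LesionSegment-class] from one scan.
#' @param scanId,timepoint scan identity.
#' @return a [ScanMetrics-class].
#' @examples
#' aggregateScan(list())  # degenerate: no metastases
#' @export
aggregateScan <- function(lesions, scanId = "scan",
                          timepoint = c("baseline", "interim")) {
  timepoint <- match.arg(timepoint)
  if (!length(lesions))
    return(new("ScanMetrics", scanId = scanId, timepoint = timepoint,
               psmaTv = 0, tlqSum = 0, meanSuvMax = NA_real_,
               nLesions = 0L))
  new("ScanMetrics", scanId = scanId, timepoint = timepoint,
      psmaTv = sum(vapply(lesions, volumeMl, numeric(1))),
      tlqSum = sum(vapply(lesions, tlqLesion, numeric(1))),
      meanSuvMax = mean(vapply(lesions, suvMax, numeric(1))),
      nLesions = length(lesions))
}

#' Classify volumetric (PSMA-TV) response
#'
#' Volumetric response is a decline in total tumor volume strictly
#' greater than 30 percent between baseline and interim. The ratio
#' baseline/interim is also reported (responders have ratio > 1/0.7); a
#' complete disappearance (interim = 0) counts as response with an
#' undefined ratio. A zero baseline leaves the response undefined.
#'
#' @param baseline,interim [ScanMetrics-class] (or bare PSMA-TV values).
#' @param declineThreshold response threshold in percent (default 30).
#' @return list: \code{tvRatio}, \code{tvDeclinePct}, \code{tvResponder}
#'   (logical, NA when undefined).
#' @examples
#' classifyTvResponse(100, 69)  # 31 percent decline: responder
#' classifyTvResponse(100, 70)  # exactly 30 percent: not a responder
#' @export
classifyTvResponse <- function(baseline, interim, declineThreshold = 30) {
  tvB <- if (is(baseline, "ScanMetrics")) psmaTv(baseline) else baseline
  tvI <- if (is(interim, "ScanMetrics")) psmaTv(interim) else interim
  if (!is.finite(tvB) || tvB <= 0)
    return(list(tvRatio = NA_real_, tvDeclinePct = NA_real_,
                tvResponder = NA))
  # (b - i) / b, not 1 - i/b: keeps the 30 percent boundary exact in
  # floating point
  decline <- 100 * (tvB - tvI) / tvB
  list(tvRatio = if (tvI > 0) tvB / tvI else NA_real_,
       tvDeclinePct = decline,
       tvResponder = decline > declineThreshold)
}

#' Classify baseline PSMA expression
#'
#' High PSMA expression is a baseline meanSUVmax strictly greater than
#' 14.3; a value of exactly 14.3 is low. Missing meanSUVmax (no lesions)
#' leaves the flag missing.
#'
#' @param baseline a [ScanMetrics-class] or a bare meanSUVmax value.
#' @param cutoff expression cutoff (default 14.3).
#' @return logical: TRUE = low expression, NA when undefined.
#' @export
classifyExpression <- function(baseline, cutoff = 14.3) {
  m <- if (is(baseline, "ScanMetrics")) meanSuvMax(baseline) else baseline
  if (!is.finite(m)) return(NA)
  !(m > cutoff)
}

#' Classify biochemical (PSA) response
#'
#' Biochemical response is a best-PSA decline strictly greater than 50
#' percent from baseline (best = minimum on-treatment PSA).
#'
#' @param psaBaseline baseline PSA in ng/ml (> 0).
#' @param psaBest best (lowest) on-treatment PSA in ng/ml.
#' @param declineThreshold response threshold in percent (default 50).
#' @return logical.
#' @examples
#' classifyPsaResponse(100, 49)  # TRUE
#' classifyPsaResponse(100, 50)  # FALSE: exactly 50 percent
#' @export
classifyPsaResponse <- function(psaBaseline, psaBest,
                                declineThreshold = 50) {
  if (!is.finite(psaBaseline) || psaBaseline <= 0)
    stop("psaBaseline must be > 0")
  100 * (psaBaseline - psaBest) / psaBaseline > declineThreshold
}

#' Per-patient response table
#'
#' Joins baseline/interim scan metrics with the clinical table and applies
#' the three response classifications.
#'
#' @param scans data.frame with columns patient_id, timepoint, psma_tv,
#'   tlq_sum, mean_suv_max, n_lesions (one row per scan; see
#'   [scanMetricsRow()]).
#' @param clinical data.frame with columns patient_id, psa, psa_best, ldh,
#'   os_months, event.
#' @param tvDeclineThreshold,psaDeclineThreshold,expressionCutoff response
#'   boundaries (defaults 30 percent, 50 percent, 14.3).
#' @return data.frame, one row per patient, with metric columns per
#'   timepoint and tv/psa/expression flags.
#' @export
buildResponseTable <- function(scans, clinical, tvDeclineThreshold = 30,
                               psaDeclineThreshold = 50,
                               expressionCutoff = 14.3) {
  b <- scans[scans$timepoint == "baseline", ]
  i <- scans[scans$timepoint == "interim", ]
  out <- merge(merge(b, i, by = "patient_id",
                     suffixes = c("_baseline", "_interim")),
               clinical, by = "patient_id")
  names(out) <- sub("^tlq_sum_", "tlq_", names(out))
  resp <- lapply(seq_len(nrow(out)), function(r)
    classifyTvResponse(out$psma_tv_baseline[r], out$psma_tv_interim[r],
                       tvDeclineThreshold))
  out$tv_ratio <- vapply(resp, `[[`, numeric(1), "tvRatio")
  out$tv_decline_pct <- vapply(resp, `[[`, numeric(1), "tvDeclinePct")
  out$tv_responder <- vapply(resp, `[[`, logical(1), "tvResponder")
  out$psa_decline_pct <- 100 * (out$psa - out$psa_best) / out$psa
  out$psa_responder <- vapply(seq_len(nrow(out)), function(r)
    classifyPsaResponse(out$psa[r], out$psa_best[r], psaDeclineThreshold),
    logical(1))
  out$low_expression <- vapply(out$mean_suv_max_baseline,
                               classifyExpression, logical(1),
                               cutoff = expressionCutoff)
  out$timepoint_baseline <- NULL
  out$timepoint_interim <- NULL
  out
}

#' One row of a per-scan metrics table
#'
#' @param metrics a [ScanMetrics-class].
#' @param patientId patient identifier.
#' @return one-row data.frame.
#' @export
scanMetricsRow <- function(metrics, patientId) {
  data.frame(patient_id = patientId, scan_id = scanId(metrics),
             timepoint = timepoint(metrics), psma_tv = psmaTv(metrics),
             tlq_sum = tlqSum(metrics), mean_suv_max = meanSuvMax(metrics),
             n_lesions = nLesions(metrics), stringsAsFactors = FALSE)
}
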