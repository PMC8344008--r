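#' Construct a CohortSimSpec
#'
#' Defaults reproduce the scale of a 33-patient radioligand-therapy
#' cohort: baseline PSMA-TV log-normal with median 138 ml and IQR 230 ml,
#' median overall survival 15 months, ~40 percent administrative
#' censoring, 18 percent low-PSMA-expression patients, and log-hazard
#' coefficients log(1.618) per unit log baseline TV and log(0.378) for
#' true volumetric response.
#'
#' @param nPatients cohort size.
#' @param betaLogTv log-hazard per unit log baseline PSMA-TV.
#' @param betaResponse log-hazard for true volumetric response.
#' @param fracLowExpression proportion with baseline meanSUVmax <= 14.3.
#' @param tvMedianMl,tvIqrMl baseline PSMA-TV log-normal (median, IQR) in ml.
#' @param censoringRate target administrative censoring proportion.
#' @param seed RNG seed.
#' @return a [CohortSimSpec-class].
#' @seealso [simulateCohort()]
#' @export
cohortSimSpec <- function(nPatients = 33L, betaLogTv = log(1.618),
                          betaResponse = log(0.378),
                          fracLowExpression = 6 / 33,
                          tvMedianMl = 138, tvIqrMl = 230,
                          censoringRate = 0.4, seed = 1L) {
  new("CohortSimSpec", nPatients = as.integer(nPatients),
      betaLogTv = betaLogTv, betaResponse = betaResponse,
      fracLowExpression = fracLowExpression, tvMedianMl = tvMedianMl,
      tvIqrMl = tvIqrMl, censoringRate = censoringRate,
      seed = as.integer(seed))
}

# Truncated log-normal draw via inverse CDF, truncation on the ratio scale.
rlnormTrunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  pl <- stats::plnorm(lower, meanlog, sdlog)
  pu <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(pl + stats::runif(n) * (pu - pl), meanlog, sdlog)
}

#' Simulate a therapy cohort with survival structure
#'
#' Per patient, baseline PSMA-TV is drawn log-normally; the interim scan
#' volume is the baseline times a decline factor. High-expression patients
#' carry a latent true-response indicator that (a) determines whether the
#' observed decline exceeds 30 percent and (b) enters the hazard through
#' \code{betaResponse}. Low-expression patients (baseline meanSUVmax <=
#' 14.3) are the confounded subgroup: their observed decline is drawn
#' independently of their hazard, low expression itself carries extra
#' hazard (log 3), and patients whose apparent decline stems from loss of
#' tracer uptake (dedifferentiation) carry a further log 3 - the mechanism
#' by which a spurious volumetric "response" accompanies poor survival.
#' Survival is exponential around a 15-month median with uniform
#' administrative censoring calibrated to \code{censoringRate}.
#'
#' @param spec a [CohortSimSpec-class].
#' @param probResponseHighExpr probability of true response among
#'   high-expression patients (default 0.45).
#' @param probSpuriousResponse probability of a spurious observed response
#'   among low-expression patients (default 0.5).
#' @param betaLowExpression,betaDediff extra log-hazards of the
#'   low-expression subgroup and of its spurious responders.
#' @param spuriousDeclineMedian median interim/baseline volume ratio of
#'   spurious responders (default 0.15: uptake loss mimics a deep,
#'   near-complete apparent response).
#' @param medianOsMonths baseline median overall survival in months.
#' @param psaLogCor correlation between log TV ratio and log PSA ratio
#'   (targets a Spearman rho near 0.67).
#' @return data.frame, one row per patient: tumor-volume metrics at both
#'   timepoints, TLQ, meanSUVmax, PSA/LDH, observed survival
#'   (\code{os_months}, \code{event}) and response/expression flags.
#' @examples
#' head(simulateCohort(cohortSimSpec(seed = 42)))
#' @export
simulateCohort <- function(spec, probResponseHighExpr = 0.45,
                           probSpuriousResponse = 0.5,
                           betaLowExpression = log(3),
                           betaDediff = log(3),
                           spuriousDeclineMedian = 0.15,
                           medianOsMonths = 15, psaLogCor = 0.687) {
  validObject(spec)
  n <- spec@nPatients
  # log-normal from (median, IQR): IQR/median = 2*sinh(z75*sdlog)
  meanlog <- log(spec@tvMedianMl)
  z75 <- stats::qnorm(0.75)
  sdlog <- asinh(spec@tvIqrMl / (2 * spec@tvMedianMl)) / z75

  withSeed(spec@seed, {
    tvB <- stats::rlnorm(n, meanlog, sdlog)
    lowExpr <- stats::runif(n) < spec@fracLowExpression
    trueResp <- !lowExpr & stats::runif(n) < probResponseHighExpr
    spurious <- lowExpr & stats::runif(n) < probSpuriousResponse
    obsResp <- trueResp | spurious

    # observed interim/baseline ratio, consistent with the response flag;
    # spurious (uptake-loss) declines are much deeper than true responses
    f <- numeric(n)
    f[trueResp] <- rlnormTrunc(sum(trueResp), log(0.45), 0.5, upper = 0.6999)
    f[spurious] <- rlnormTrunc(sum(spurious), log(spuriousDeclineMedian),
                               0.6, upper = 0.6999)
    f[!obsResp] <- rlnormTrunc(sum(!obsResp), log(1.0), 0.35, lower = 0.7)
    tvI <- tvB * f

    meanSuvMaxB <- numeric(n)
    meanSuvMaxB[!lowExpr] <- rlnormTrunc(sum(!lowExpr), log(25), 0.3,
                                         lower = 14.3001)
    meanSuvMaxB[lowExpr] <- stats::runif(sum(lowExpr), 6, 14.3)
    meanSuvMaxI <- meanSuvMaxB * stats::rlnorm(n, 0, 0.15)
    suvMeanEff <- 0.3 * meanSuvMaxB * stats::rlnorm(n, 0, 0.2)
    tlqB <- tvB / suvMeanEff
    tlqI <- tvI / suvMeanEff

    # hazard: log TV effect + true-response benefit + confounded subgroup
    lp <- spec@betaLogTv * (log(tvB) - meanlog) +
      spec@betaResponse * trueResp +
      ifelse(lowExpr, betaLowExpression + betaDediff * spurious, 0)
    lp <- lp - mean(lp)   # anchor the marginal median OS, HRs unchanged
    death <- stats::rexp(n, rate = log(2) / medianOsMonths * exp(lp))

    if (spec@censoringRate > 0) {
      target <- spec@censoringRate
      cfrac <- function(tau) mean(pmin(death / tau, 1)) - target
      hi <- max(death) * 2
      tau <- if (cfrac(hi) > 0) hi
             else stats::uniroot(cfrac, c(min(death) / 1e3, hi))$root
      cens <- stats::runif(n, 0, tau)
      os <- pmin(death, cens)
      event <- death <= cens
    } else {
      os <- death
      event <- rep(TRUE, n)
    }
    os <- pmax(os, 1e-3)

    # best PSA ratio correlated with the TV ratio on the log scale
    zf <- as.numeric(scale(log(f)))
    if (any(!is.finite(zf))) zf <- rep(0, n)  # degenerate: constant ratios
    logPsaRatio <- log(0.6) +
      0.9 * (psaLogCor * zf + sqrt(1 - psaLogCor^2) * stats::rnorm(n))
    psa <- stats::rlnorm(n, log(146), 1.2)
    psaBest <- psa * exp(logPsaRatio)
    ldh <- stats::rlnorm(n, log(282), 0.5)

    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      psma_tv_baseline = tvB, psma_tv_interim = tvI,
      tlq_baseline = tlqB, tlq_interim = tlqI,
      mean_suv_max_baseline = meanSuvMaxB,
      mean_suv_max_interim = meanSuvMaxI,
      psa = psa, psa_best = psaBest, ldh = ldh,
      os_months = os, event = event,
      tv_ratio = tvB / tvI,
      tv_decline_pct = 100 * (tvB - tvI) / tvB,
      tv_responder = 100 * (tvB - tvI) / tvB > 30,
      psa_decline_pct = 100 * (psa - psaBest) / psa,
      psa_responder = 100 * (psa - psaBest) / psa > 50,
      low_expression = !(meanSuvMaxB > 14.3),
      true_responder = trueResp,
      stringsAsFactors = FALSE)
  })
}
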