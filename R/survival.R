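#' Two-sample log-rank z-statistic
#'
#' Standardized log-rank statistic computed directly from the risk sets:
#' z = (O - E) / sqrt(V) for group 2, with the hypergeometric variance at
#' each distinct event time. This equals the Cox partial-likelihood score
#' test at beta = 0, which the test suite uses as a cross-check.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = death).
#' @param group two-level grouping (logical or factor-like).
#' @return list: \code{z}, \code{chisq} (= z^2), \code{observed},
#'   \code{expected} for the second group.
#' @export
logrankStatistic <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  if (length(unique(g)) != 2L) stop("group must have exactly two levels")
  event <- as.integer(event)
  times <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in times) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n2 <- sum(atRisk & g == 2L)
    d <- sum(event == 1L & time == t)
    d2 <- sum(event == 1L & time == t & g == 2L)
    O <- O + d2
    E <- E + d * n2 / n
    if (n > 1L) V <- V + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1L)
  }
  z <- if (V > 0) (O - E) / sqrt(V) else 0
  list(z = z, chisq = z^2, observed = O, expected = E)
}

# Nelson-Aalen cumulative hazard evaluated at each subject's own time.
nelsonAalenAt <- function(time, event) {
  ord <- order(time)
  times <- sort(unique(time[event == 1]))
  H <- vapply(time, function(ti) {
    ts <- times[times <= ti]
    if (!length(ts)) return(0)
    sum(vapply(ts, function(t)
      sum(event == 1 & time == t) / sum(time >= t), numeric(1)))
  }, numeric(1))
  H
}

# Apply the cohort's log-transform policy to a covariate column.
transformCovariate <- function(x, logTransform) {
  if (!logTransform) return(x)
  if (is.logical(x)) return(x)
  bad <- is.finite(x) & x <= 0
  if (any(bad))
    stop("non-positive value under log transform in rows: ",
         paste(which(bad), collapse = ", "))
  log(x)
}

#' Cox proportional-hazards fit on a cohort table
#'
#' Wraps \code{survival::coxph} (Efron tie handling) over
#' \code{Surv(os_months, event)}. Continuous covariates are natural-log
#' transformed by default, matching the analysis plan; logical covariates
#' are used as 0/1 indicators. Rows with missing covariates are dropped
#' complete-case and the used n is reported.
#'
#' @param cohort data.frame with os_months, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param logTransform log-transform continuous covariates (default TRUE).
#' @return list of class \code{coxFit}: \code{model} (the coxph fit),
#'   \code{table} (per-covariate HR, 95 percent CI, Wald p), \code{lrtP}
#'   (likelihood-ratio p), \code{nUsed}, \code{nDropped}.
#' @examples
#' co <- simulateCohort(cohortSimSpec(nPatients = 60, seed = 11))
#' coxFit(co, "psma_tv_baseline")$table
#' @export
coxFit <- function(cohort, covariates, logTransform = TRUE) {
  dat <- cohort[, c("os_months", "event", covariates), drop = FALSE]
  complete <- stats::complete.cases(dat)
  nDropped <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  if (sum(dat$event) < 2L) stop("fewer than 2 events")
  for (cv in covariates) {
    if (length(unique(dat[[cv]])) < 2L)
      stop("covariate '", cv, "' is constant: hazard ratio undefined")
    dat[[cv]] <- transformCovariate(dat[[cv]], logTransform)
  }
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  tab <- data.frame(
    covariate = rownames(s$coefficients),
    hr = s$conf.int[, "exp(coef)"],
    ciLower = s$conf.int[, 3L],
    ciUpper = s$conf.int[, 4L],
    waldP = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = fit, table = tab,
                 lrtP = as.numeric(s$logtest["pvalue"]),
                 nUsed = nrow(dat), nDropped = nDropped,
                 logTransform = logTransform, covariates = covariates),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Cox PH fit (Efron ties), n =", x$nUsed,
      if (x$nDropped) paste0("(", x$nDropped, " dropped)"), "\n")
  print(x$table, digits = 4)
  cat("LR test p =", format.pval(x$lrtP, digits = 3), "\n")
  invisible(x)
}

#' Kaplan-Meier comparison of two groups
#'
#' Product-limit estimates per group with medians (earliest time at which
#' survival drops to 0.5 or below), two-sided log-rank test, and the
#' hazard ratio from a single-covariate Cox model on the group indicator.
#'
#' @param cohort data.frame with os_months and event.
#' @param groupFlag logical/two-level vector, or the name of a column.
#' @return list: \code{fit} (survfit), \code{medians} (named per group),
#'   \code{logrankP}, \code{logrankZ}, \code{hr}, \code{hrCi},
#'   \code{groupSizes}.
#' @export
kmLogrank <- function(cohort, groupFlag) {
  g <- if (is.character(groupFlag) && length(groupFlag) == 1L)
    cohort[[groupFlag]] else groupFlag
  g <- factor(g)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("need two nonempty groups")
  dat <- data.frame(os_months = cohort$os_months, event = cohort$event,
                    group = g)
  fit <- survival::survfit(survival::Surv(os_months, event) ~ group,
                           data = dat)
  med <- summary(fit)$table[, "median"]
  sd0 <- survival::survdiff(survival::Surv(os_months, event) ~ group,
                            data = dat)
  lrP <- stats::pchisq(sd0$chisq, df = 1L, lower.tail = FALSE)
  lr <- logrankStatistic(dat$os_months, dat$event, dat$group)
  cx <- survival::coxph(survival::Surv(os_months, event) ~ group,
                        data = dat, ties = "efron")
  ci <- summary(cx)$conf.int
  list(fit = fit, medians = stats::setNames(as.numeric(med), levels(g)),
       logrankP = lrP, logrankZ = lr$z,
       hr = as.numeric(exp(stats::coef(cx))),
       hrCi = c(ci[1L, 3L], ci[1L, 4L]),
       groupSizes = as.integer(table(g)))
}

#' Median split of a continuous covariate
#'
#' High group = value strictly above the median (midpoint convention for
#' even n); ties at the median go to the low group. All-equal covariates
#' cannot be split and raise an error.
#'
#' @param cohort data.frame (or NULL when \code{covariate} is a vector).
#' @param covariate column name or numeric vector.
#' @return logical vector, TRUE = high group.
#' @export
medianBinarize <- function(cohort, covariate) {
  x <- if (is.character(covariate) && length(covariate) == 1L)
    cohort[[covariate]] else covariate
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 2L) stop("covariate present for fewer than 2 rows")
  med <- stats::median(x, na.rm = TRUE)
  hi <- x > med
  if (!any(hi, na.rm = TRUE) || all(hi, na.rm = TRUE))
    stop("degenerate grouping: covariate cannot be split at its median")
  hi
}

# Log-rank scores (martingale residuals of the null model): the linear
# statistic sum(scores[x <= cut]) standardized by its permutation moments
# is the maximally-selected rank statistic of the maxstat ecosystem.
logrankScores <- function(time, event) {
  as.numeric(event) - nelsonAalenAt(time, event)
}

#' Maximally selected rank statistic cutoff
#'
#' Finds the cutoff of a continuous covariate maximizing the absolute
#' standardized two-sample log-rank statistic over all admissible splits.
#' Candidate cutoffs are midpoints between consecutive distinct sorted
#' values whose induced groups both hold at least \code{minProp} of the
#' patients; the smallest cutoff wins ties. The statistic is the linear
#' log-rank-scores statistic with conditional (permutation)
#' standardization; a permutation p-value for the maximum is available
#' via \code{nPerm} (the point estimate is the primary output).
#'
#' @param cohort data.frame with os_months and event.
#' @param covariate column name or numeric vector.
#' @param minProp minimum proportion of patients per group (default 0.1).
#' @param nPerm permutations for the adjusted p-value of the maximum;
#'   0 (default) skips it, 10000 is a sensible choice when needed.
#' @param seed RNG seed for the permutation p-value.
#' @return list of class \code{maxstatCutoff}: \code{cutoff},
#'   \code{statistic} (max |z|), \code{groupSizes}, \code{candidates}
#'   (data.frame of cutoff/statistic pairs), \code{permP} (or NA).
#' @export
maxstatCutoff <- function(cohort, covariate, minProp = 0.1, nPerm = 0L,
                          seed = 1L) {
  x <- if (is.character(covariate) && length(covariate) == 1L)
    cohort[[covariate]] else covariate
  ok <- is.finite(x) & is.finite(cohort$os_months)
  x <- x[ok]
  time <- cohort$os_months[ok]
  event <- as.numeric(cohort$event[ok])
  n <- length(x)
  sc <- logrankScores(time, event)

  ord <- order(x)
  xs <- x[ord]
  scs <- sc[ord]
  distinct <- which(diff(xs) > 0)        # split after position i
  mLow <- distinct                       # group sizes: low = x <= cut
  adm <- mLow >= ceiling(minProp * n) & (n - mLow) >= ceiling(minProp * n)
  if (sum(adm) < 1L)
    stop("fewer than 2 distinct covariate values in the admissible range")
  cuts <- (xs[distinct[adm]] + xs[distinct[adm] + 1L]) / 2
  mAdm <- mLow[adm]

  csum <- cumsum(scs)
  meanSc <- mean(sc)
  varSc <- mean((sc - meanSc)^2)
  stdStat <- function(Tm, m)
    (Tm - m * meanSc) / sqrt(m * (n - m) / (n - 1) * varSc)
  zs <- stdStat(csum[distinct[adm]], mAdm)

  best <- which.max(abs(zs))             # first max = smallest cutoff
  permP <- NA_real_
  if (nPerm > 0L) {
    obs <- abs(zs[best])
    exceed <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(b) {
        sp <- sample(sc)
        cs <- cumsum(sp)
        max(abs(stdStat(cs[distinct[adm]], mAdm))) >= obs
      }, logical(1)))
    })
    permP <- (exceed + 1) / (nPerm + 1)
  }
  structure(list(cutoff = cuts[best], statistic = abs(zs[best]),
                 groupSizes = c(low = mAdm[best], high = n - mAdm[best]),
                 candidates = data.frame(cutoff = cuts, z = zs),
                 permP = permP, n = n),
            class = "maxstatCutoff")
}

#' @export
print.maxstatCutoff <- function(x, ...) {
  cat("Maximally selected rank statistic: cutoff",
      format(x$cutoff, digits = 5), "| max |z| =",
      format(x$statistic, digits = 4), "| groups",
      paste(x$groupSizes, collapse = "/"),
      if (!is.na(x$permP)) paste("| perm p =", format(x$permP, digits = 3)),
      "\n")
  invisible(x)
}

#' Martingale residuals
#'
#' For a fitted Cox model, residual_i = event_i - estimated cumulative
#' hazard at the subject's time times its risk score (Breslow baseline).
#' For the null model this reduces to event_i minus the Nelson-Aalen
#' cumulative hazard. Residuals lie in (-Inf, 1] and sum to zero.
#'
#' @param cohort data.frame with os_months and event.
#' @param fit a [coxFit()] result, or NULL for the null model.
#' @return numeric residuals (aligned with the rows the fit used).
#' @export
martingaleResiduals <- function(cohort, fit = NULL) {
  if (is.null(fit))
    return(as.numeric(cohort$event) -
             nelsonAalenAt(cohort$os_months, as.numeric(cohort$event)))
  as.numeric(stats::residuals(fit$model, type = "martingale"))
}

#' Correlate volumetric and biochemical response
#'
#' Spearman correlation between PSMA-TV decline and best PSA decline, and
#' a Wilcoxon rank-sum comparison of TV decline by PSA-responder status.
#' Exact p-values are used for n <= 10 pairs, the normal approximation
#' otherwise.
#'
#' @param cohort data.frame with tv_decline_pct, psa_decline_pct,
#'   psa_responder.
#' @return list: \code{spearmanRho}, \code{spearmanP}, \code{wilcoxonP},
#'   \code{medianDeclineByPsa} (named: responder / nonresponder), \code{n}.
#' @export
correlateAndCompare <- function(cohort) {
  ok <- is.finite(cohort$tv_decline_pct) & is.finite(cohort$psa_decline_pct)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 complete pairs")
  exact <- n <= 10L
  ct <- suppressWarnings(
    stats::cor.test(cohort$tv_decline_pct[ok], cohort$psa_decline_pct[ok],
                    method = "spearman", exact = exact))
  grp <- cohort$psa_responder[ok]
  wilcoxonP <- NA_real_
  med <- c(responder = NA_real_, nonresponder = NA_real_)
  if (length(unique(grp)) == 2L) {
    wt <- suppressWarnings(
      stats::wilcox.test(cohort$tv_decline_pct[ok][grp],
                         cohort$tv_decline_pct[ok][!grp], exact = exact))
    wilcoxonP <- wt$p.value
    med <- c(responder = stats::median(cohort$tv_decline_pct[ok][grp]),
             nonresponder = stats::median(cohort$tv_decline_pct[ok][!grp]))
  }
  list(spearmanRho = as.numeric(ct$estimate), spearmanP = ct$p.value,
       wilcoxonP = wilcoxonP, medianDeclineByPsa = med, n = n)
}
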