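test_that("KM medians and log-rank behave on the hand-worked fixture", {
  fx <- kmFixture()
  # fully separated groups: the companion Cox HR is degenerate by design
  km <- suppressWarnings(kmLogrank(fx, fx$group))
  expect_equal(as.numeric(km$medians["A"]), 4)
  expect_equal(as.numeric(km$medians["B"]), 12)
  expect_lt(km$logrankP, 0.2)    # small n, but clearly separated groups
  expect_identical(km$groupSizes, c(3L, 3L))
  # identical groups: statistic exactly zero, p = 1
  dup <- rbind(fx[1:3, ], fx[1:3, ])
  dup$group <- rep(c("A", "B"), each = 3)
  km0 <- kmLogrank(dup, dup$group)
  expect_equal(km0$logrankZ, 0)
  expect_equal(km0$logrankP, 1)
  expect_error(kmLogrank(fx, rep("A", 6)), "two nonempty groups")
})

test_that("KM estimate is a valid survival curve", {
  co <- simulateCohort(cohortSimSpec(nPatients = 80, seed = 21))
  km <- kmLogrank(co, medianBinarize(co, "psma_tv_baseline"))
  s <- km$fit$surv
  strata <- rep(seq_along(km$fit$strata), km$fit$strata)
  for (g in unique(strata)) {
    sg <- s[strata == g]
    expect_true(all(diff(sg) <= 1e-12))   # non-increasing
    expect_lte(sg[1], 1)
  }
})

test_that("median split sends ties to the low group", {
  expect_identical(medianBinarize(NULL, c(1, 2, 3, 4)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(medianBinarize(NULL, c(1, 2, 3)),
                   c(FALSE, FALSE, TRUE))      # 2 is the median: low
  expect_error(medianBinarize(NULL, c(5, 5, 5)), "degenerate")
})

test_that("the package log-rank z matches the Cox score test", {
  for (s in 1:8) {
    set.seed(200 + s)
    # continuous times: the identity is exact only without ties
    fx <- data.frame(os_months = rexp(30, 1 / 12), event = runif(30) < 0.7,
                     x = rlnorm(30, 3, 1))
    grp <- fx$x > median(fx$x)
    lr <- logrankStatistic(fx$os_months, fx$event, grp)
    cx <- survival::coxph(survival::Surv(os_months, event) ~ grp, data = fx)
    expect_equal(lr$chisq, as.numeric(summary(cx)$sctest["test"]),
                 tolerance = 1e-6)
    sd0 <- survival::survdiff(survival::Surv(os_months, event) ~ grp,
                              data = fx)
    expect_equal(lr$chisq, sd0$chisq, tolerance = 1e-6)
  }
})

test_that("Cox fits report HR, CI and complete-case n", {
  co <- simulateCohort(cohortSimSpec(nPatients = 120, seed = 31))
  co$psa[c(3, 7)] <- NA
  f <- coxFit(co, c("psma_tv_baseline", "psa", "ldh"))
  expect_identical(f$nUsed, 118L)
  expect_identical(f$nDropped, 2L)
  expect_true(all(f$table$ciLower <= f$table$hr + 1e-12))
  expect_true(all(f$table$hr <= f$table$ciUpper + 1e-12))
  expect_true(all(f$table$hr > 0))
  expect_error(coxFit(transform(co, flat = 1), "flat"), "constant")
  bad <- co; bad$psma_tv_baseline[1] <- -1
  expect_error(coxFit(bad, "psma_tv_baseline"), "non-positive")
  few <- co[1:5, ]; few$event <- FALSE
  expect_error(coxFit(few, "psma_tv_baseline"), "events")
})

test_that("null-effect Cox confidence intervals cover 1", {
  nrep <- 100
  cover <- 0L
  for (r in seq_len(nrep)) {
    co <- simulateCohort(cohortSimSpec(nPatients = 100, betaLogTv = 0,
                                       betaResponse = 0,
                                       fracLowExpression = 0,
                                       seed = 50000 + r))
    f <- coxFit(co, "psma_tv_baseline")
    if (f$table$ciLower <= 1 && 1 <= f$table$ciUpper) cover <- cover + 1L
  }
  expect_gte(cover, 93L)
})

test_that("martingale residuals sum to zero and respect signs", {
  co <- simulateCohort(cohortSimSpec(nPatients = 90, seed = 41))
  rNull <- martingaleResiduals(co)
  expect_lt(abs(sum(rNull)), 1e-8)
  expect_true(all(rNull <= 1 + 1e-12))
  f <- coxFit(co, "psma_tv_baseline")
  rFit <- martingaleResiduals(co, f)
  expect_lt(abs(sum(rFit)), 1e-8)
  # a patient censored at the first event time has residual -H(t1) < 0
  fx <- data.frame(os_months = c(2, 2, 5, 8), event = c(TRUE, FALSE, TRUE,
                                                        TRUE))
  r <- martingaleResiduals(fx)
  expect_equal(r[2], -1 / 4)   # Nelson-Aalen at t=2 is 1/4
  expect_lt(r[2], 0)
})

test_that("maxstat cutoff equals exhaustive search on random fixtures", {
  for (s in 1:12) {
    fx <- randomSurvivalFixture(sample(20:40, 1), 300 + s)
    got <- maxstatCutoff(fx, "x")
    want <- oracleMaxstat(fx$os_months, as.numeric(fx$event), fx$x)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$statistic, want$z, tolerance = 1e-10)
  }
})

test_that("maxstat separates two subpopulations at the gap midpoint", {
  set.seed(9)
  x <- c(rnorm(15, 1, 0.05), rnorm(15, 10, 0.05))
  fx <- data.frame(os_months = c(rexp(15, 1 / 5), rexp(15, 1 / 40)) + 0.1,
                   event = TRUE, x = x)
  res <- maxstatCutoff(fx, "x")
  expect_gt(res$cutoff, max(x[1:15]))
  expect_lt(res$cutoff, min(x[16:30]))
  expect_equal(res$cutoff, (max(x[1:15]) + min(x[16:30])) / 2)
  # exactly two distinct values: the single admissible midpoint
  fx2 <- data.frame(os_months = rexp(20, 1 / 10) + 0.1, event = TRUE,
                    x = rep(c(1, 3), 10))
  expect_equal(maxstatCutoff(fx2, "x")$cutoff, 2)
  # all-equal covariate cannot be split
  fx3 <- transform(fx2, x = 1)
  expect_error(maxstatCutoff(fx3, "x"), "distinct")
})

test_that("correlation and rank-sum comparisons behave on worked cases", {
  fx <- data.frame(tv_decline_pct = 1:8, psa_decline_pct = (1:8)^2,
                   psa_responder = rep(c(FALSE, TRUE), each = 4))
  out <- correlateAndCompare(fx)
  expect_equal(out$spearmanRho, 1)
  fx$psa_decline_pct <- -(1:8)
  expect_equal(correlateAndCompare(fx)$spearmanRho, -1)
  expect_error(correlateAndCompare(fx[1:2, ]), "pairs")
})

test_that("simulated decline correlation concentrates near its target", {
  nrep <- 60
  ok <- 0L
  for (r in seq_len(nrep)) {
    co <- simulateCohort(cohortSimSpec(nPatients = 33, seed = 60000 + r))
    rho <- correlateAndCompare(co)$spearmanRho
    if (abs(rho - 0.67) <= 0.25) ok <- ok + 1L
  }
  expect_gte(ok / nrep, 0.9)
})

test_that("the outcome report carries the full analysis plan", {
  co <- simulateCohort(cohortSimSpec(nPatients = 132, seed = 77))
  outDir <- tempfile("report")
  rep <- runOutcomeAnalysis(co, outDir = outDir)
  expect_s3_class(rep, "outcomeReport")
  expect_true(all(c("uni_psma_tv_baseline", "multi_tlq_baseline",
                    "uni_tv_ratio") %in% rep$coxTable$model))
  expect_identical(sort(rep$headline$cohort),
                   c("full", "no_low_expression"))
  expect_true(all(file.exists(file.path(outDir,
    c("cox_results.csv", "km_curves.csv", "martingale.csv",
      "report.json")))))
  js <- jsonlite::read_json(file.path(outDir, "report.json"))
  expect_equal(js$n, 132)
  unlink(outDir, recursive = TRUE)
})
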