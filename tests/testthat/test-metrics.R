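test_that("scan aggregation sums volumes and TLQ and averages SUVmax", {
  lesions <- list(makeLesion(1, 1250, 10), makeLesion(2, 2500, 20),
                  makeLesion(3, 3750, 30))
  m <- aggregateScan(lesions)
  expect_equal(psmaTv(m), 60)                      # 10 + 20 + 30 ml
  expect_equal(meanSuvMax(m), 20)
  expect_equal(tlqSum(m), 10 / 10 + 20 / 20 + 30 / 30)
  expect_identical(nLesions(m), 3L)
  # empty scan: zero volumes, missing meanSUVmax
  e <- aggregateScan(list())
  expect_equal(psmaTv(e), 0)
  expect_equal(tlqSum(e), 0)
  expect_true(is.na(meanSuvMax(e)))
})

test_that("PSMA-TV is additive under lesion splitting", {
  whole <- list(makeLesion(1, 1000, c(5, 15)))
  split2 <- list(makeLesion(1, 400, c(5, 15)), makeLesion(2, 600, c(5, 15)))
  expect_equal(psmaTv(aggregateScan(whole)), psmaTv(aggregateScan(split2)))
})

test_that("per-lesion TLQ is exactly volume over SUVmean", {
  set.seed(1)
  for (r in 1:20) {
    l <- makeLesion(1, sample(10:500, 1), runif(5, 1, 30))
    expect_equal(tlqLesion(l), volumeMl(l) / suvMean(l), tolerance = 1e-12)
  }
  # scan-level TLQ bounded by TV over extreme SUVmeans
  lesions <- list(makeLesion(1, 1000, c(2, 4)), makeLesion(2, 500, c(8, 12)))
  m <- aggregateScan(lesions)
  sm <- sapply(lesions, suvMean)
  expect_gte(tlqSum(m), psmaTv(m) / max(sm) - 1e-12)
  expect_lte(tlqSum(m), psmaTv(m) / min(sm) + 1e-12)
})

test_that("volumetric response uses a strict 30 percent boundary", {
  expect_true(classifyTvResponse(100, 69)$tvResponder)    # 31 percent
  expect_false(classifyTvResponse(100, 70)$tvResponder)   # exactly 30
  r <- classifyTvResponse(138, 107)                       # cohort medians
  expect_false(r$tvResponder)
  expect_equal(r$tvDeclinePct, 100 * (1 - 107 / 138))
  expect_equal(r$tvRatio, 138 / 107)
  # complete disappearance: responder with undefined ratio
  z <- classifyTvResponse(100, 0)
  expect_true(z$tvResponder)
  expect_true(is.na(z$tvRatio))
  expect_equal(z$tvDeclinePct, 100)
  # zero baseline: undefined
  expect_true(is.na(classifyTvResponse(0, 10)$tvResponder))
})

test_that("volumetric response classification is scale invariant", {
  set.seed(2)
  for (r in 1:25) {
    b <- runif(1, 10, 500); i <- runif(1, 1, 500); c0 <- runif(1, 0.01, 100)
    expect_identical(classifyTvResponse(b, i)$tvResponder,
                     classifyTvResponse(c0 * b, c0 * i)$tvResponder)
  }
})

test_that("expression and PSA boundaries are strict", {
  expect_true(classifyExpression(14.3))    # exactly 14.3 counts as low
  expect_false(classifyExpression(14.31))
  expect_true(is.na(classifyExpression(NA_real_)))
  expect_true(classifyPsaResponse(100, 49))
  expect_false(classifyPsaResponse(100, 50))   # exactly 50 percent
  expect_false(classifyPsaResponse(100, 150))  # PSA increase
  expect_error(classifyPsaResponse(0, 10), "psaBaseline")
})

test_that("each patient gets exactly one response state", {
  co <- simulateCohort(cohortSimSpec(nPatients = 150, seed = 3))
  states <- ifelse(is.na(co$tv_responder), "missing",
                   ifelse(co$tv_responder, "responder", "non-responder"))
  expect_true(all(states %in% c("missing", "responder", "non-responder")))
  expect_equal(sum(co$tv_responder, na.rm = TRUE) +
                 sum(!co$tv_responder, na.rm = TRUE) +
                 sum(is.na(co$tv_responder)), 150)
})

test_that("response table joins scans with clinical data", {
  scans <- rbind(
    data.frame(patient_id = "P1", scan_id = "P1_b", timepoint = "baseline",
               psma_tv = 100, tlq_sum = 20, mean_suv_max = 20, n_lesions = 3),
    data.frame(patient_id = "P1", scan_id = "P1_i", timepoint = "interim",
               psma_tv = 60, tlq_sum = 12, mean_suv_max = 18, n_lesions = 2),
    data.frame(patient_id = "P2", scan_id = "P2_b", timepoint = "baseline",
               psma_tv = 50, tlq_sum = 10, mean_suv_max = 10, n_lesions = 1),
    data.frame(patient_id = "P2", scan_id = "P2_i", timepoint = "interim",
               psma_tv = 45, tlq_sum = 9, mean_suv_max = 9, n_lesions = 1))
  clinical <- data.frame(patient_id = c("P1", "P2"), psa = c(100, 80),
                         psa_best = c(40, 60), ldh = c(250, 300),
                         os_months = c(20, 8), event = c(FALSE, TRUE))
  tab <- buildResponseTable(scans, clinical)
  expect_equal(nrow(tab), 2)
  expect_true(tab$tv_responder[tab$patient_id == "P1"])   # 40 percent drop
  expect_false(tab$tv_responder[tab$patient_id == "P2"])  # 10 percent drop
  expect_true(tab$psa_responder[tab$patient_id == "P1"])  # 60 percent drop
  expect_false(tab$low_expression[tab$patient_id == "P1"])
  expect_true(tab$low_expression[tab$patient_id == "P2"])
  expect_true(all(c("tlq_baseline", "tlq_interim") %in% names(tab)))
})
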