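# Synthetic cohort generator: marginal shape, prevalence calibration,
# outcome-model properties, reproducibility.

test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  expect_false(anyDuplicated(a$patient_id) > 0)
  # and the serialized form is byte-identical too
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("covariate marginals match their configured shape", {
  coh <- generate_cohort(cohort_config(n = 5000, seed = 7))
  expect_true(all(coh$age >= 42 & coh$age <= 79))
  expect_lt(abs(median(coh$age) - 66), 2)
  freq <- table(bmi_category(coh$bmi)) / nrow(coh)
  expect_lt(abs(freq[["normal"]] - 0.25), 0.05)
  expect_lt(abs(freq[["overweight"]] - 0.45), 0.05)
  expect_lt(abs(freq[["obese"]] - 0.295), 0.05)
  gfreq <- table(factor(coh$gleason, levels = 6:10)) / nrow(coh)
  expect_lt(abs(gfreq[["7"]] - 0.66), 0.05)
  expect_true(all(coh$psa >= 0))
  expect_gt(mean(coh$psa), median(coh$psa))    # right skew
  expect_true(all(coh$duration_first_admission >= 1))
  expect_lt(abs(mean(long_stay(coh$duration_first_admission)) - 0.22), 0.05)
})

test_that("event rate is calibrated to the target prevalence", {
  cfg <- cohort_config(n = 5000, target_prevalence = 0.011, seed = 1)
  b0 <- calibrate_intercept(cfg)
  rates <- vapply(1:50, function(s) {
    cfg_s <- cohort_config(n = 5000, target_prevalence = 0.011,
                           intercept = b0, seed = s)
    mean(generate_cohort(cfg_s)$vte_90d)
  }, numeric(1))
  mc_se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.011), 3 * mc_se)
})

test_that("realized event counts stay inside the binomial band", {
  # n = 522 at 1.1% prevalence: expectation ~5.7 events per cohort
  counts <- vapply(1:100, function(s) {
    sum(generate_cohort(cohort_config(n = 522, seed = s,
                                      effects = numeric(0)))$vte_90d)
  }, numeric(1))
  band <- qbinom(c(0.005, 0.995), 522, 0.011)
  expect_gt(mean(counts >= band[1] & counts <= band[2]), 0.95)
  expect_lt(abs(mean(counts) - 522 * 0.011), 3 * sd(counts) / 10)
})

test_that("intercept calibration: closed forms, Monte-Carlo target, monotonicity", {
  expect_equal(calibrate_intercept(cohort_config(effects = numeric(0),
                                                 target_prevalence = 0.011)),
               qlogis(0.011))
  expect_equal(calibrate_intercept(cohort_config(effects = numeric(0),
                                                 target_prevalence = 0.5)),
               0)
  # nonzero effects: achieved mean probability within Monte-Carlo error
  cfg <- cohort_config(n = 1000, target_prevalence = 0.011, seed = 3)
  coh <- generate_cohort(cohort_config(n = 2e5, target_prevalence = 0.011,
                                       seed = 99, intercept = 0))
  p <- event_probability(coh, cfg)
  expect_lt(abs(mean(p) - 0.011), 3 * sd(p) / sqrt(length(p)) + 1e-4)
  # monotone in the target
  b_lo <- calibrate_intercept(cohort_config(target_prevalence = 0.011, seed = 3))
  b_hi <- calibrate_intercept(cohort_config(target_prevalence = 0.05, seed = 3))
  expect_gt(b_hi, b_lo)
})

test_that("raising a positive-effect covariate never lowers event probability", {
  cfg <- cohort_config(n = 200, seed = 5)
  coh <- generate_cohort(cfg)
  for (v in c("duration_first_admission", "psa", "bmi", "age")) {
    bumped <- coh
    bumped[[v]] <- bumped[[v]] + 1
    expect_true(all(event_probability(bumped, cfg) >=
                      event_probability(coh, cfg)),
                info = v)
  }
})

test_that("null effects produce no covariate-outcome association", {
  cfg <- cohort_config(n = 4000, effects = numeric(0), seed = 11)
  coh <- generate_cohort(cfg)
  expect_equal(unique(event_probability(coh, cfg)), 0.011)
  # any fixed linear combination of covariates is uninformative
  lp <- coh$psa + coh$bmi + coh$duration_first_admission
  expect_lt(abs(auc(lp, coh$vte_90d) - 0.5), 0.12)
})

test_that("invalid configurations fail with the offending covariate named", {
  expect_error(cohort_config(target_prevalence = 0), "target_prevalence")
  expect_error(cohort_config(n = 0), "n")
  expect_error(cohort_config(effects = c(nonexistent = 1)), "nonexistent")
  expect_error(
    cohort_config(marginal_params = list(psa = list(meanlog = 1, sdlog = -1))),
    "psa"
  )
  expect_error(
    cohort_config(marginal_params = list(
      duration_first_admission = list(size = -2, mu = 2))),
    "duration_first_admission"
  )
  # unreachable prevalence under extreme effects
  expect_error(
    calibrate_intercept(cohort_config(target_prevalence = 1e-4,
                                      effects = c(psa = 50))),
    "calibration"
  )
})
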