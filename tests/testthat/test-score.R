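# Score construction: banding, threshold selection, system assembly,
# the built-in preset, and patient scoring.

test_that("banding reproduces the reference point assignments", {
  expect_identical(band_points(30.1300915), 5L)
  expect_identical(band_points(29.9357324), 4L)
  expect_identical(band_points(24.3406184), 4L)
  expect_identical(band_points(5.2599722), 2L)
  expect_identical(band_points(1.17630012), 2L)
  expect_identical(band_points(15.0), 3L)
  expect_identical(band_points(0.5), NA_integer_)   # below omission bound
  expect_identical(band_points(1), NA_integer_)     # "above" is strict
  expect_identical(band_points(30.0), 4L)           # boundary: next band down
  expect_error(band_points(-1), "non-negative")
})

test_that("banding is a non-decreasing step function with jumps only at band bounds", {
  grid <- seq(0, 60, by = 0.25)
  pts <- band_points(grid)
  vals <- ifelse(is.na(pts), 0L, pts)
  expect_true(all(diff(vals) >= 0))
  jumps <- grid[which(diff(vals) != 0) + 1]
  # strict 'above': the jump happens just past each bound
  expect_true(all(vapply(jumps, function(j) {
    any(abs(j - 0.25 - c(30, 20, 10, 1)) < 1e-9)
  }, logical(1))))
})

test_that("invalid banding schemes are rejected", {
  expect_error(banding_scheme(data.frame(lower_bound = c(10, 20),
                                         points = c(3L, 2L))),
               "decreasing")
  expect_error(banding_scheme(data.frame(lower_bound = c(20, 10),
                                         points = c(2L, 3L))),
               "decreasing")
  expect_error(banding_scheme(omit_below = 5), "omit_below")
})

test_that("threshold selection finds the left edge of the largest jump", {
  expect_equal(select_threshold(step_curve(8)), 8)
  # strictly constant curve: no-threshold signal
  expect_true(is.na(select_threshold(
    data.frame(grid = 0:9, effect = rep(0.3, 10)))))
  # monotone linear curve: all steps tie, first grid value wins
  expect_equal(select_threshold(
    data.frame(grid = 0:9, effect = seq(0, 0.9, by = 0.1))), 0)
  # rounding to the variable's natural resolution
  expect_equal(select_threshold(step_curve(8.3, grid = seq(0, 15, 0.1)),
                                resolution = 1), 8)
  expect_error(select_threshold(data.frame(grid = 1, effect = 1)),
               "two grid points")
})

test_that("a scoring system is assembled from importances, curves and forced rules", {
  imp <- reference_importances
  thresholds <- c(duration_first_admission = 8, psa = 10, bmi = 30,
                  age = 65, clotting_disease_count = 0,
                  n_comorbidities = 3, mets_score = 3,
                  neurological_disease_count = 0)
  curves <- lapply(thresholds, function(t) {
    step_curve(t, grid = seq(t - 5, t + 5, by = 1))
  })
  sys <- build_scoring_system(imp, curves,
                              forced_rules = score_rule("gleason", 6, 1))
  expect_s3_class(sys, "scoring_system")
  expect_equal(nrow(sys$rules), 9)
  expect_equal(sys$max_total, 24)
  expect_equal(sys$rules$threshold[sys$rules$variable == "psa"], 10)
  expect_equal(sys$rules$source[sys$rules$variable == "gleason"], "forced")

  # empty importance table + one forced rule
  empty <- data.frame(variable = character(0),
                      relative_importance = numeric(0))
  solo <- build_scoring_system(empty, list(),
                               forced_rules = score_rule("bmi", 30, 2))
  expect_equal(nrow(solo$rules), 1)
  expect_equal(solo$max_total, 2)

  # a missing curve for a non-omitted variable is a build error naming it
  expect_error(build_scoring_system(imp, curves[-1]),
               "duration_first_admission")
  # forced rule overrides a banded rule on the same variable
  over <- build_scoring_system(imp, curves,
                               forced_rules = score_rule("psa", 20, 3))
  expect_equal(nrow(over$rules), 8)
  psa_rule <- over$rules[over$rules$variable == "psa", ]
  expect_equal(psa_rule$threshold, 20)
  expect_equal(psa_rule$points, 3L)
})

test_that("the preset system carries the nine reference rules and max total 24", {
  sys <- preset_scoring_system()
  expect_equal(nrow(sys$rules), 9)
  expect_equal(sys$max_total, 24)
  rule <- function(v) sys$rules[sys$rules$variable == v, ]
  expect_equal(rule("psa")$threshold, 10)
  expect_equal(rule("psa")$points, 4L)
  expect_equal(rule("duration_first_admission")$threshold, 8)
  expect_equal(rule("duration_first_admission")$points, 5L)
  expect_equal(rule("gleason")$source, "forced")
  expect_equal(sum(sys$rules$points), sys$max_total)
})

test_that("patients are scored by strict threshold conditions", {
  sys <- preset_scoring_system()
  expect_equal(score_patient(all_conditions_record(), sys), 24)
  expect_equal(score_patient(make_record(), sys), 0)
  # hand sum: duration 10 (5) + PSA 12 (4) + BMI 31 (4)
  expect_equal(score_patient(make_record(duration_first_admission = 10L,
                                         psa = 12, bmi = 31), sys), 13)
  # boundary values score 0 for that rule (strict 'greater than')
  expect_equal(score_patient(make_record(psa = 10, bmi = 30,
                                         duration_first_admission = 8L,
                                         age = 65L), sys), 0)
  # missing-data policies
  rec <- make_record()
  rec$psa <- NA_real_
  expect_error(score_patient(rec, sys), "psa")
  expect_equal(score_patient(rec, sys, missing = "zero"), 0)
})

test_that("cohort scoring preserves order, length and bounds", {
  sys <- preset_scoring_system()
  expect_identical(score_cohort(make_record()[0, ], sys), integer(0))
  expect_equal(score_cohort(all_conditions_record(), sys), 24)
  coh <- generate_cohort(cohort_config(n = 400, seed = 6))
  s <- score_cohort(coh, sys)
  expect_length(s, nrow(coh))
  expect_true(all(s >= 0 & s <= sys$max_total))
  perm <- with_seed(1, sample.int(nrow(coh)))
  expect_identical(score_cohort(coh[perm, ], sys), s[perm])
  # per-patient context on missing data
  coh2 <- coh
  coh2$bmi[3] <- NA
  expect_error(score_cohort(coh2, sys), coh2$patient_id[3])
})

test_that("raising any rule covariate never decreases the score", {
  sys <- preset_scoring_system()
  coh <- generate_cohort(cohort_config(n = 200, seed = 8))
  base <- score_cohort(coh, sys)
  for (v in sys$rules$variable) {
    bumped <- coh
    bumped[[v]] <- bumped[[v]] + 1
    expect_true(all(score_cohort(bumped, sys) >= base), info = v)
  }
})

test_that("a scoring system survives a serialization round trip", {
  sys <- preset_scoring_system()
  path <- withr::local_tempfile(fileext = ".json")
  write_scoring_system(sys, path)
  back <- read_scoring_system(path)
  expect_equal(back$max_total, sys$max_total)
  coh <- generate_cohort(cohort_config(n = 300, seed = 10))
  expect_identical(score_cohort(coh, back), score_cohort(coh, sys))
})
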