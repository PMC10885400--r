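# Cut-point estimation: simulation estimator vs enumeration oracle,
# calibration rule, Youden and bootstrap comparators.

test_that("degenerate score sets give exact simulation cut-offs", {
  one <- simulation_cutoff(7, B = 50, m = 5, seed = 1)
  expect_equal(one$value, 7)
  expect_equal(one$mc_se, 0)
  same <- simulation_cutoff(c(3, 3, 3), B = 200, m = 4, seed = 2)
  expect_equal(same$value, 3)
  expect_equal(same$mc_se, 0)
  expect_error(simulation_cutoff(numeric(0)), "non-empty")
})

test_that("the enumeration oracle matches hand-checkable cases", {
  # frozen from an independent full 6^5 enumeration via stats::quantile
  expect_equal(exact_expected_quantile(vte_scores, m = 5), 6.178498,
               tolerance = 1e-6)
  expect_equal(
    exact_expected_quantile(vte_scores, m = 5,
                            qspec = quantile_spec(interpolation = "nearest")),
    5.957305, tolerance = 1e-6
  )
  expect_equal(exact_expected_quantile(c(4, 4, 4), m = 3), 4)
  # m = 1: the quantile is the single draw, expectation is the mean
  expect_equal(exact_expected_quantile(c(0, 1), m = 1), 0.5)
  # the linear rule at m = 5, p = 0.025 weights order stats 0.9/0.1
  e1 <- exact_expected_quantile(vte_scores, m = 5,
                                qspec = quantile_spec(interpolation = "nearest"))
  e2 <- mean(apply(as.matrix(expand.grid(rep(list(seq_along(vte_scores)), 5))),
                   1, function(i) sort(vte_scores[i])[2]))
  expect_equal(exact_expected_quantile(vte_scores, m = 5),
               0.9 * e1 + 0.1 * e2, tolerance = 1e-9)
  expect_error(exact_expected_quantile(1:40, m = 5), "enumeration limit")
})

test_that("the simulation estimator converges to the enumeration oracle", {
  exact <- exact_expected_quantile(vte_scores, m = 5)
  for (s in 1:20) {
    est <- simulation_cutoff(vte_scores, B = 10000, m = 5, seed = s)
    expect_lt(abs(est$value - exact), 3 * est$mc_se)
  }
})

test_that("Monte-Carlo error scales as one over root B", {
  a <- simulation_cutoff(vte_scores, B = 10000, m = 5, seed = 3)
  b <- simulation_cutoff(vte_scores, B = 40000, m = 5, seed = 3)
  expect_lt(abs(b$mc_se / a$mc_se - 0.5), 0.1)
})

test_that("simulation cut-offs are bounded, deterministic and translation-equivariant", {
  est <- simulation_cutoff(vte_scores, B = 2000, m = 5, seed = 5)
  expect_gte(est$value, min(vte_scores))
  expect_lte(est$value, max(vte_scores))
  expect_identical(est$value,
                   simulation_cutoff(vte_scores, B = 2000, m = 5,
                                     seed = 5)$value)
  shifted <- simulation_cutoff(vte_scores + 10, B = 2000, m = 5, seed = 5)
  expect_equal(shifted$value, est$value + 10)
  expect_equal(
    exact_expected_quantile(vte_scores + 10, m = 4),
    exact_expected_quantile(vte_scores, m = 4) + 10
  )
})

test_that("calibration lowers the cut-off to the minimum positive score", {
  cal <- calibrate_cutoff(6.1, vte_scores)
  expect_equal(cal$value, 5)
  expect_equal(cal$method, "calibrated")
  # no positive below the estimate: unchanged
  expect_equal(calibrate_cutoff(6.1, c(7, 9, 14))$value, 6.1)
  # idempotent, and never raises the cut-off
  twice <- calibrate_cutoff(cal, vte_scores)
  expect_equal(twice$value, cal$value)
  est <- simulation_cutoff(vte_scores, B = 2000, seed = 1)
  expect_lte(calibrate_cutoff(est, vte_scores)$value, est$value)
})

test_that("the Youden cut-off matches an exhaustive scan", {
  # perfectly separable: J = 1 at the smallest positive score
  sep <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(sep$value, 8)
  expect_equal(sep$params$J, 1)
  # interleaved classes: compare against a brute-force scan
  scores <- c(1, 3, 2, 4)
  labels <- c(0, 0, 1, 1)
  brute <- sapply(sort(unique(scores)), function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  })
  best <- sort(unique(scores))[which.max(brute)]
  expect_equal(youden_cutoff(scores, labels)$value, best)
  # random instances
  for (s in 1:10) {
    dat <- with_seed(s, list(x = sample(0:10, 40, replace = TRUE),
                             y = rbinom(40, 1, 0.3)))
    if (length(unique(dat$y)) < 2) next
    cand <- sort(unique(dat$x))
    j <- sapply(cand, function(t) {
      mean(dat$x[dat$y == 1] >= t) + mean(dat$x[dat$y == 0] < t) - 1
    })
    expect_equal(youden_cutoff(dat$x, dat$y)$value, cand[which.max(j)])
  }
  # all scores identical: J = 0 everywhere, that score returned
  same <- youden_cutoff(rep(4, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$value, 4)
  expect_equal(same$params$J, 0)
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the bootstrap cut-off is stratified, reproducible and consistent", {
  # perfect separation with one distinct value per class: every stratified
  # resample yields the same threshold
  boo <- bootstrap_cutoff(c(1, 1, 8, 8), c(0, 0, 1, 1), B = 100, seed = 1)
  expect_equal(boo$value, 8)
  expect_equal(boo$mc_se, 0)
  # B = 1 with a fixed seed is reproducible
  b1 <- bootstrap_cutoff(c(1, 5, 3, 8, 9, 2), c(0, 1, 0, 1, 1, 0),
                         B = 1, seed = 7)
  b2 <- bootstrap_cutoff(c(1, 5, 3, 8, 9, 2), c(0, 1, 0, 1, 1, 0),
                         B = 1, seed = 7)
  expect_identical(b1$value, b2$value)
  # large n, fixed separation: bootstrap mean near the full-sample Youden
  dat <- with_seed(11, {
    n <- 600
    y <- rbinom(n, 1, 0.3)
    x <- round(rnorm(n, mean = 2 * y, sd = 1), 1)
    list(x = x, y = y)
  })
  full <- youden_cutoff(dat$x, dat$y)$value
  boo2 <- bootstrap_cutoff(dat$x, dat$y, B = 400, seed = 2)
  expect_lt(abs(boo2$value - full), max(3 * boo2$mc_se, 0.3))
})

test_that("cut-off estimates tabulate for comparison", {
  tab <- cutoff_table(
    simulation_cutoff(vte_scores, B = 500, seed = 1),
    calibrate_cutoff(6.1, vte_scores),
    youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1)),
    bootstrap_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1), B = 50, seed = 1)
  )
  expect_equal(tab$method, c("simulation", "calibrated", "youden",
                             "bootstrap"))
  expect_true(all(c("value", "B", "m", "p", "seed", "mc_se") %in%
                    names(tab)))
})
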