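# Cut-point estimation for the risk score: the simulation-based
# lower-quantile estimator with its exact enumeration oracle and the
# lower-to-minimum-positive calibration rule, plus Youden and bootstrap
# comparators.

#' Quantile specification for the simulation cut-off
#'
#' @param p Quantile level in (0, 1); default 0.025 (the lower 2.5%
#'   point of each resampled score distribution).
#' @param interpolation `"linear"` (default) for the Hyndman-Fan
#'   definition-7 order-statistic interpolation (the common statistics
#'   default: with sorted sample x(1..n) and h = (n-1)p, the quantile is
#'   x(floor(h)+1) + (h-floor(h)) (x(floor(h)+2) - x(floor(h)+1))), or
#'   `"nearest"` for the inverse-CDF rule returning a single order
#'   statistic.
#' @return An object of class `quantile_spec`.
#' @export
#' @examples
#' quantile_spec()
quantile_spec <- function(p = 0.025, interpolation = c("linear", "nearest")) {
  assert_scalar_number(p, "p", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  interpolation <- match.arg(interpolation)
  structure(list(p = p, interpolation = interpolation,
                 type = if (interpolation == "linear") 7L else 1L),
            class = "quantile_spec")
}

sample_quantile <- function(x, qspec) {
  quantile(x, probs = qspec$p, type = qspec$type, names = FALSE)
}

new_cutoff_estimate <- function(method, value, params, mc_se = NA_real_) {
  structure(list(method = method, value = value, params = params,
                 mc_se = mc_se),
            class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat(sprintf("<cutoff_estimate: %s> value %.4g", x$method, x$value))
  if (is.finite(x$mc_se)) cat(sprintf(" (mc_se %.4g)", x$mc_se))
  cat("\n")
  invisible(x)
}

check_positive_scores <- function(positive_scores) {
  if (!is.numeric(positive_scores) || length(positive_scores) == 0L ||
      anyNA(positive_scores)) {
    stop("`positive_scores` must be a non-empty numeric vector",
         call. = FALSE)
  }
  as.numeric(positive_scores)
}

#' Simulation-based cut-off for a risk score
#'
#' Resamples the scores of the VTE-positive patients `B` times (size `m`,
#' with replacement), computes the lower `p` quantile of each resample,
#' and returns the mean of the `B` quantiles as the cut-point, together
#' with its Monte-Carlo standard error. This pools the information in a
#' handful of positive cases into a stable threshold estimate.
#'
#' @param positive_scores Numeric scores of the outcome-positive
#'   patients.
#' @param B Number of resampled datasets (default 10000).
#' @param m Size of each resample (default 5).
#' @param qspec A [quantile_spec()].
#' @param seed Integer seed; the estimate is deterministic given the
#'   seed.
#' @return A `cutoff_estimate` with `method = "simulation"`, the
#'   resampling parameters, and `mc_se = sd/sqrt(B)`.
#' @export
#' @examples
#' simulation_cutoff(c(5, 6, 9, 14, 15, 15), seed = 1)
simulation_cutoff <- function(positive_scores, B = 10000L, m = 5L,
                              qspec = quantile_spec(), seed = 1L) {
  positive_scores <- check_positive_scores(positive_scores)
  B <- assert_count(B, "B"); m <- assert_count(m, "m")
  stopifnot(inherits(qspec, "quantile_spec"))
  n <- length(positive_scores)
  q <- with_seed(seed, {
    idx <- matrix(sample.int(n, B * m, replace = TRUE), nrow = B)
    vals <- matrix(positive_scores[idx], nrow = B)
    apply(vals, 1L, sample_quantile, qspec = qspec)
  })
  new_cutoff_estimate(
    "simulation", mean(q),
    params = list(B = B, m = m, p = qspec$p,
                  interpolation = qspec$interpolation, seed = seed),
    mc_se = sd(q) / sqrt(B)
  )
}

#' Exact expected resample quantile (enumeration oracle)
#'
#' Exact value the simulation cut-off converges to as the number of
#' resamples grows: the expectation of the `p`-level quantile of a
#' with-replacement resample of size `m`, computed by enumerating all
#' `length(positive_scores)^m` equally likely ordered resamples.
#'
#' @inheritParams simulation_cutoff
#' @param enumeration_limit Maximum number of ordered resamples to
#'   enumerate (default 1e7); beyond it, use Monte-Carlo via
#'   [simulation_cutoff()].
#' @return The exact expected quantile.
#' @export
#' @examples
#' exact_expected_quantile(c(5, 6, 9, 14, 15, 15), m = 5) # about 6.18
exact_expected_quantile <- function(positive_scores, m = 5L,
                                    qspec = quantile_spec(),
                                    enumeration_limit = 1e7) {
  positive_scores <- check_positive_scores(positive_scores)
  m <- assert_count(m, "m")
  stopifnot(inherits(qspec, "quantile_spec"))
  n <- length(positive_scores)
  total <- n^m
  if (total > enumeration_limit) {
    stop("enumeration limit exceeded (", n, "^", m, " resamples); ",
         "use simulation_cutoff() for a Monte-Carlo estimate",
         call. = FALSE)
  }
  total <- as.double(total)
  acc <- 0
  chunk <- 1e5
  done <- 0
  while (done < total) {
    k <- min(chunk, total - done)
    r <- done + seq_len(k) - 1          # 0-based resample indices
    idx <- matrix(0L, nrow = k, ncol = m)
    for (j in seq_len(m)) {
      idx[, j] <- (r %/% n^(j - 1)) %% n + 1
    }
    vals <- matrix(positive_scores[idx], nrow = k)
    acc <- acc + sum(apply(vals, 1L, sample_quantile, qspec = qspec))
    done <- done + k
  }
  acc / total
}

#' Calibrate a simulated cut-off against the observed positive scores
#'
#' The calibration rule lowers a simulated cut-off to the minimum
#' observed positive score whenever any positive patient falls below it,
#' so that no outcome-positive patient is classified low-risk; otherwise
#' the cut-off is returned unchanged. The operation is idempotent.
#'
#' @param estimate A `cutoff_estimate` (or a bare numeric cut-off).
#' @param positive_scores Scores of the outcome-positive patients.
#' @return A `cutoff_estimate` with `method = "calibrated"`.
#' @export
#' @examples
#' calibrate_cutoff(6.1, c(5, 6, 9, 14, 15, 15))$value # 5
calibrate_cutoff <- function(estimate, positive_scores) {
  positive_scores <- check_positive_scores(positive_scores)
  value <- if (inherits(estimate, "cutoff_estimate")) estimate$value
           else assert_scalar_number(estimate, "estimate")
  lo <- min(positive_scores)
  new_cutoff_estimate(
    "calibrated", if (lo < value) lo else value,
    params = c(
      if (inherits(estimate, "cutoff_estimate")) estimate$params,
      list(calibrated_from = value, min_positive = lo)
    )
  )
}

youden_scan <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  candidates <- sort(unique(scores))
  j <- vapply(candidates, function(t) {
    mean(pos >= t) + mean(neg < t) - 1
  }, numeric(1))
  best <- which.max(j)                  # first max -> smallest threshold
  list(threshold = candidates[best], J = j[best],
       candidates = candidates, j = j)
}

#' Youden-index cut-off
#'
#' Scans all distinct observed scores as candidate thresholds (high risk
#' means score greater than or equal to the threshold) and returns the
#' one maximizing Youden's J = sensitivity + specificity - 1. Ties are
#' broken toward the smallest threshold, i.e. toward higher sensitivity.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (0/1 or logical), both classes present.
#' @return A `cutoff_estimate` with `method = "youden"` and the achieved
#'   J in `params`.
#' @export
#' @examples
#' youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))$value # 8
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  scan <- youden_scan(scores, labels)
  new_cutoff_estimate("youden", scan$threshold,
                      params = list(J = scan$J))
}

#' Bootstrap cut-off
#'
#' Mean of the Youden-optimal threshold over `B` stratified bootstrap
#' resamples (resampling with replacement within each outcome class, so
#' class counts are preserved and no resample is degenerate).
#'
#' @inheritParams youden_cutoff
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; deterministic given the seed.
#' @return A `cutoff_estimate` with `method = "bootstrap"` and
#'   `mc_se = sd/sqrt(B)`.
#' @export
#' @examples
#' bootstrap_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1), B = 50, seed = 1)
bootstrap_cutoff <- function(scores, labels, B = 1000L, seed = 1L) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  B <- assert_count(B, "B")
  ipos <- which(labels == 1L)
  ineg <- which(labels == 0L)
  thr <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- c(sample(ipos, length(ipos), replace = TRUE),
                sample(ineg, length(ineg), replace = TRUE))
      youden_scan(scores[take], labels[take])$threshold
    }, numeric(1))
  })
  new_cutoff_estimate("bootstrap", mean(thr),
                      params = list(B = B, seed = seed),
                      mc_se = sd(thr) / sqrt(B))
}

#' Tabulate cut-off estimates for comparison
#'
#' @param ... `cutoff_estimate` objects.
#' @return Data frame with columns method, value, B, m, p, seed, mc_se
#'   (missing parameters as `NA`).
#' @export
#' @examples
#' cutoff_table(simulation_cutoff(c(5, 6, 9), seed = 1),
#'              youden_cutoff(c(1, 5, 6, 9), c(0, 1, 1, 1)))
cutoff_table <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && is.list(ests[[1]]) &&
      !inherits(ests[[1]], "cutoff_estimate")) {
    ests <- ests[[1]]
  }
  rows <- lapply(ests, function(e) {
    stopifnot(inherits(e, "cutoff_estimate"))
    g <- function(k) if (is.null(e$params[[k]])) NA else e$params[[k]]
    data.frame(method = e$method, value = e$value,
               B = as.numeric(g("B")), m = as.numeric(g("m")),
               p = as.numeric(g("p")), seed = as.numeric(g("seed")),
               mc_se = e$mc_se, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
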