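# Discrimination and threshold-performance assessment: Mann-Whitney AUC,
# ROC points, bootstrap AUC confidence interval, confusion metrics at a
# cut-off, and small-sample group comparisons.

#' Area under the ROC curve (Mann-Whitney)
#'
#' AUC as the probability of correct pairwise ranking:
#' `P(score_pos > score_neg) + 0.5 P(tie)` over all positive-negative
#' pairs, computed from mid-ranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcome (0/1 or logical), both classes present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(1, 2, 3, 2, 4), c(0, 0, 0, 1, 1)) # 0.75
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  r <- rank(scores)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' One point per distinct score threshold (high risk means score greater
#' than or equal to the threshold) plus the endpoints (0, 0) and (1, 1).
#' The trapezoidal area over these points equals the Mann-Whitney
#' [auc()], ties receiving half credit.
#'
#' @inheritParams auc
#' @return Data frame with columns `threshold`, `sensitivity`, `fpr`
#'   (1 - specificity), sorted by decreasing threshold so the curve runs
#'   from (0, 0) to (1, 1).
#' @export
#' @examples
#' roc_points(c(1, 2, 8, 9), c(0, 0, 1, 1))
roc_points <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- data.frame(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thresholds, function(t) mean(neg >= t), numeric(1))
  )
  rownames(out) <- NULL
  out
}

trapezoid_area <- function(points) {
  o <- order(points$fpr, points$sensitivity)
  x <- points$fpr[o]; y <- points$sensitivity[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval of `B` stratified bootstrap AUCs (resampling with
#' replacement within each class, so every resample contains both
#' classes).
#'
#' @inheritParams auc
#' @param B Number of bootstrap resamples (default 2000, minimum 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; deterministic given the seed.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' auc_ci(c(1, 2, 8, 9), c(0, 0, 1, 1), B = 200, seed = 1)
auc_ci <- function(scores, labels, B = 2000L, level = 0.95, seed = 1L) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  B <- assert_count(B, "B", min = 100L)
  assert_scalar_number(level, "level", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  ipos <- which(labels == 1L)
  ineg <- which(labels == 0L)
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- c(sample(ipos, length(ipos), replace = TRUE),
                sample(ineg, length(ineg), replace = TRUE))
      auc(scores[take], labels[take])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' ROC summary with AUC and bootstrap confidence interval
#'
#' @inheritParams auc_ci
#' @return An object of class `roc_summary`: ROC `points`, `auc`,
#'   `ci_low`/`ci_high`, `ci_method`, `B`, `level` and `seed`.
#' @export
#' @examples
#' roc_summary(c(1, 2, 8, 9), c(0, 0, 1, 1), B = 200, seed = 1)
roc_summary <- function(scores, labels, B = 2000L, level = 0.95, seed = 1L) {
  a <- auc(scores, labels)
  ci <- auc_ci(scores, labels, B = B, level = level, seed = seed)
  structure(
    list(points = roc_points(scores, labels), auc = a,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         ci_method = "stratified bootstrap percentile",
         B = as.integer(B), level = level, seed = as.integer(seed)),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC %.3f (%d%% CI %.3f-%.3f, %s, B=%d)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$ci_method, x$B))
  invisible(x)
}

#' Confusion metrics at a score cut-off
#'
#' Patients with score greater than or equal to the cut-off are called
#' high risk. Rates whose denominator is zero are undefined and returned
#' as `NA` (not 0).
#'
#' @inheritParams auc
#' @param cutoff Score threshold.
#' @return An object of class `confusion_metrics`: `cutoff`, counts
#'   `tp`, `fp`, `tn`, `fn`, and `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
#' @examples
#' confusion_metrics(c(2, 5, 6, 9), c(0, 1, 1, 1), cutoff = 5)
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- check_binary_labels(labels, require_both = FALSE)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  assert_scalar_number(cutoff, "cutoff")
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn)),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> cutoff %g: tp %d fp %d tn %d fn %d | sens %s spec %s ppv %s npv %s\n",
    x$cutoff, x$tp, x$fp, x$tn, x$fn,
    format(x$sensitivity, digits = 3), format(x$specificity, digits = 3),
    format(x$ppv, digits = 3), format(x$npv, digits = 3)
  ))
  invisible(x)
}

#' Compare a variable between outcome groups
#'
#' Small-sample conventions for clinical baseline tables: categorical
#' variables (character, factor, logical) are tested with Fisher's exact
#' test (falling back to the chi-square test when the exact computation
#' is infeasible for a large sparse table); continuous variables with the
#' Wilcoxon rank-sum test.
#'
#' @param cohort Data frame of patient records.
#' @param variable Column to compare.
#' @param grouping Binary grouping column (default `"vte_90d"`); both
#'   groups must be non-empty.
#' @param test `"auto"` (default), `"fisher"`, `"chi-square"` or
#'   `"rank-sum"`.
#' @return A list of class `group_comparison`: `variable`, `test`,
#'   `statistic`, `p_value`, and per-group `summaries`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 400, seed = 5))
#' compare_groups(coh, "bmi")
compare_groups <- function(cohort, variable, grouping = "vte_90d",
                           test = c("auto", "fisher", "chi-square",
                                    "rank-sum")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(cohort))
  if (!variable %in% names(cohort)) {
    stop("unknown variable `", variable, "`", call. = FALSE)
  }
  if (!grouping %in% names(cohort)) {
    stop("unknown grouping column `", grouping, "`", call. = FALSE)
  }
  g <- check_binary_labels(cohort[[grouping]], require_both = FALSE)
  x <- cohort[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  if (!all(c(0L, 1L) %in% g)) {
    stop("grouping must yield two non-empty groups", call. = FALSE)
  }
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  if (test == "auto") test <- if (categorical) "fisher" else "rank-sum"
  if (test %in% c("fisher", "chi-square")) {
    tab <- table(x, g)
    if (test == "fisher") {
      ft <- tryCatch(fisher.test(tab),
                     error = function(e) NULL)
      if (is.null(ft)) {
        test <- "chi-square"
      } else {
        res <- list(statistic = NA_real_, p_value = ft$p.value)
      }
    }
    if (test == "chi-square") {
      ct <- suppressWarnings(chisq.test(tab))
      res <- list(statistic = unname(ct$statistic), p_value = ct$p.value)
    }
    summaries <- lapply(c(`0` = 0L, `1` = 1L), function(gr) {
      table(x[g == gr])
    })
  } else {
    if (!is.numeric(x)) {
      stop("rank-sum test requires a numeric variable", call. = FALSE)
    }
    wt <- suppressWarnings(wilcox.test(x[g == 1L], x[g == 0L]))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
    summaries <- lapply(c(`0` = 0L, `1` = 1L), function(gr) {
      c(median = median(x[g == gr]), min = min(x[g == gr]),
        max = max(x[g == gr]))
    })
  }
  structure(
    list(variable = variable, test = test, statistic = res$statistic,
         p_value = res$p_value, summaries = summaries),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): p = %.4g\n",
              x$variable, x$test, x$p_value))
  invisible(x)
}
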