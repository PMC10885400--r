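# Score construction: band relative importances into integer points,
# pick per-variable thresholds from partial-dependence curves, combine
# with forced domain-knowledge rules, and score patients.

#' Importance-banding scheme
#'
#' Maps relative-importance percentages to integer score points. The
#' default bands score importances strictly above 30, 20, 10 and 1 as
#' 5, 4, 3 and 2 points respectively; importances not strictly above the
#' lowest band bound are omitted from the score.
#'
#' @param bands Two-column matrix-like input or data frame with columns
#'   `lower_bound` (importance percentage, strictly decreasing) and
#'   `points` (positive integers, strictly decreasing).
#' @param omit_below Importances below this value are always omitted;
#'   must not exceed the smallest lower bound. Default 1.
#' @return An object of class `banding_scheme`.
#' @export
#' @examples
#' banding_scheme()
banding_scheme <- function(bands = data.frame(
                             lower_bound = c(30, 20, 10, 1),
                             points = c(5L, 4L, 3L, 2L)),
                           omit_below = 1) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("lower_bound", "points") %in% names(bands)),
            nrow(bands) >= 1L)
  if (any(diff(bands$lower_bound) >= 0)) {
    stop("band lower bounds must be strictly decreasing", call. = FALSE)
  }
  if (any(diff(bands$points) >= 0) || any(bands$points < 1) ||
      any(bands$points != round(bands$points))) {
    stop("band points must be strictly decreasing positive integers",
         call. = FALSE)
  }
  assert_scalar_number(omit_below, "omit_below",
                       upper = min(bands$lower_bound))
  structure(list(bands = bands, omit_below = omit_below),
            class = "banding_scheme")
}

#' Band a relative importance into score points
#'
#' Returns the points of the highest band whose lower bound the
#' importance strictly exceeds ("above" is strict everywhere: an
#' importance of exactly 30 falls into the 20-band). Importances below
#' `omit_below`, or not strictly above the lowest band bound, are omitted
#' and returned as `NA`.
#'
#' @param importance Numeric vector of relative importances (>= 0).
#' @param scheme A [banding_scheme()].
#' @return Integer vector of points, `NA` where the variable is omitted.
#' @export
#' @examples
#' band_points(c(30.13, 24.34, 0.5))
band_points <- function(importance, scheme = banding_scheme()) {
  stopifnot(inherits(scheme, "banding_scheme"))
  if (!is.numeric(importance) || anyNA(importance)) {
    stop("`importance` must be numeric without missing values",
         call. = FALSE)
  }
  if (any(importance < 0)) {
    stop("`importance` must be non-negative", call. = FALSE)
  }
  vapply(importance, function(imp) {
    if (imp < scheme$omit_below) return(NA_integer_)
    hit <- which(imp > scheme$bands$lower_bound)
    if (!length(hit)) return(NA_integer_)
    as.integer(scheme$bands$points[hit[1]])
  }, integer(1))
}

#' Select a scoring threshold from a partial-dependence curve
#'
#' Automates the visual reading of a partial-dependence plot: the
#' threshold is the grid value at the left edge of the largest
#' single-step increase of the curve, i.e. the last covariate value
#' *before* the predicted risk jumps, matching strictly-greater-than
#' scoring conditions. Ties are broken toward the smallest grid value.
#'
#' @param curve A [partial_dependence()] curve (or any data frame with
#'   `grid` and `effect` columns) with at least two grid points.
#' @param resolution Optional rounding resolution in the covariate's
#'   natural units (e.g. 1 for integer days or whole ng/mL); the returned
#'   threshold is rounded to the nearest multiple.
#' @return The threshold value, or `NA` if the curve has no increasing
#'   step (flat or decreasing curve) — callers must then fall back to a
#'   configured default.
#' @export
#' @examples
#' curve <- data.frame(grid = 0:10, effect = c(rep(0.1, 9), 0.6, 0.6))
#' select_threshold(curve) # 8: effect jumps between 8 and 9
select_threshold <- function(curve, resolution = NULL) {
  stopifnot(is.data.frame(curve), all(c("grid", "effect") %in% names(curve)))
  if (nrow(curve) < 2L) {
    stop("`curve` must have at least two grid points", call. = FALSE)
  }
  steps <- diff(curve$effect)
  if (max(steps) <= 0) return(NA_real_)
  # float-tolerant tie handling: steps within a sliver of the maximum are
  # ties, broken toward the smallest grid value
  tol <- 1e-9 * diff(range(curve$effect))
  idx <- which(steps >= max(steps) - tol)[1]
  thr <- curve$grid[idx]
  if (!is.null(resolution)) {
    assert_scalar_number(resolution, "resolution", 0, Inf,
                         strict_lower = TRUE)
    thr <- round(thr / resolution) * resolution
  }
  thr
}

#' Create a single scoring rule
#'
#' A rule awards `points` when a patient's `variable` is strictly greater
#' than `threshold`.
#'
#' @param variable Covariate name from the patient schema.
#' @param threshold Finite numeric threshold in the variable's units.
#' @param points Positive integer points.
#' @param source `"banded"` (derived from importances) or `"forced"`
#'   (domain knowledge).
#' @return One-row data frame.
#' @export
#' @examples
#' score_rule("gleason", 6, 1)
score_rule <- function(variable, threshold, points, source = "forced") {
  stopifnot(is.character(variable), length(variable) == 1L)
  assert_scalar_number(threshold, "threshold")
  points <- assert_count(points, "points")
  source <- match.arg(source, c("banded", "forced"))
  data.frame(variable = variable, threshold = threshold,
             points = points, source = source, stringsAsFactors = FALSE)
}

new_scoring_system <- function(rules) {
  rownames(rules) <- NULL
  structure(list(rules = rules, max_total = sum(rules$points)),
            class = "scoring_system")
}

#' Build a scoring system from model summaries
#'
#' One banded rule is created per variable whose importance is not
#' omitted by the banding scheme: its points come from [band_points()]
#' and its threshold from [select_threshold()] applied to that variable's
#' partial-dependence curve. Forced rules are then appended, overriding
#' any banded rule for the same variable.
#'
#' @param importances An [relative_importance()] table (columns
#'   `variable`, `relative_importance`).
#' @param curves Named list of partial-dependence curves, one per
#'   non-omitted variable.
#' @param scheme A [banding_scheme()].
#' @param forced_rules Optional data frame of [score_rule()] rows.
#' @param resolution Named list/vector of per-variable rounding
#'   resolutions passed to [select_threshold()] (default: round every
#'   threshold to the nearest integer, the natural resolution of days,
#'   years, ng/mL and kg/m^2).
#' @param fallback_thresholds Named vector of thresholds to use for
#'   variables whose curve has no increasing step.
#' @return An object of class `scoring_system`.
#' @export
#' @examples
#' imp <- data.frame(variable = "psa", relative_importance = 29.9)
#' crv <- list(psa = data.frame(grid = c(5, 10, 15),
#'                              effect = c(0.1, 0.1, 0.5)))
#' build_scoring_system(imp, crv,
#'                      forced_rules = score_rule("gleason", 6, 1))
build_scoring_system <- function(importances, curves,
                                 scheme = banding_scheme(),
                                 forced_rules = NULL, resolution = 1,
                                 fallback_thresholds = NULL) {
  stopifnot(is.data.frame(importances),
            all(c("variable", "relative_importance") %in% names(importances)))
  pts <- band_points(importances$relative_importance, scheme)
  keep <- which(!is.na(pts))
  rules <- lapply(keep, function(i) {
    v <- importances$variable[i]
    if (is.null(curves[[v]])) {
      stop("build error: no partial-dependence curve for non-omitted ",
           "variable `", v, "`", call. = FALSE)
    }
    res <- if (length(resolution) > 1L || !is.null(names(resolution))) {
      resolution[[v]]
    } else {
      resolution
    }
    thr <- select_threshold(curves[[v]], resolution = res)
    if (is.na(thr)) {
      thr <- fallback_thresholds[[v]]
      if (is.null(thr)) {
        stop("build error: flat partial-dependence curve for `", v,
             "` and no fallback threshold configured", call. = FALSE)
      }
    }
    score_rule(v, thr, pts[i], source = "banded")
  })
  rules <- do.call(rbind, c(rules, list(NULL)))
  if (!is.null(forced_rules)) {
    forced_rules <- as.data.frame(forced_rules)
    forced_rules$source <- "forced"
    if (!is.null(rules)) {
      rules <- rules[!rules$variable %in% forced_rules$variable, ,
                     drop = FALSE]
    }
    rules <- rbind(rules, forced_rules)
  }
  if (is.null(rules) || nrow(rules) == 0L) {
    stop("build error: no rules survive banding and no forced rules given",
         call. = FALSE)
  }
  if (anyDuplicated(rules$variable)) {
    stop("at most one rule per variable is allowed", call. = FALSE)
  }
  new_scoring_system(rules)
}

#' The built-in nine-rule VTE scoring system
#'
#' The reference risk-stratified scoring system for 90-day VTE after
#' minimally invasive prostatectomy: duration of first admission > 8 days
#' scores 5; PSA > 10 ng/mL and BMI > 30 kg/m^2 score 4 each; age > 65
#' years, any clotting disease, more than 3 comorbidities, METS score
#' > 3 and any neurological disease score 2 each; Gleason score > 6
#' (a forced, literature-motivated rule) scores 1. Maximum total 24.
#'
#' @return An object of class `scoring_system` with nine rules.
#' @export
#' @examples
#' sys <- preset_scoring_system()
#' sys$max_total # 24
preset_scoring_system <- function() {
  rules <- rbind(
    score_rule("duration_first_admission", 8, 5, "banded"),
    score_rule("psa", 10, 4, "banded"),
    score_rule("bmi", 30, 4, "banded"),
    score_rule("age", 65, 2, "banded"),
    score_rule("clotting_disease_count", 0, 2, "banded"),
    score_rule("n_comorbidities", 3, 2, "banded"),
    score_rule("mets_score", 3, 2, "banded"),
    score_rule("neurological_disease_count", 0, 2, "banded"),
    score_rule("gleason", 6, 1, "forced")
  )
  new_scoring_system(rules)
}

#' Score a single patient
#'
#' The patient's score is the sum of points over all rules whose
#' condition holds, a condition being "covariate strictly greater than
#' threshold". Boundary values (equal to the threshold) score 0 for that
#' rule.
#'
#' @param record A one-row data frame or named list with every covariate
#'   the system references.
#' @param system A `scoring_system`.
#' @param missing Missing-covariate policy: `"strict"` (default) raises
#'   an error; `"zero"` treats the condition as unmet.
#' @return Integer score in \[0, max_total\].
#' @export
#' @examples
#' rec <- list(duration_first_admission = 10, psa = 12, bmi = 31,
#'             age = 60, clotting_disease_count = 0, n_comorbidities = 1,
#'             mets_score = 2, neurological_disease_count = 0, gleason = 6)
#' score_patient(rec, preset_scoring_system()) # 5 + 4 + 4 = 13
score_patient <- function(record, system, missing = c("strict", "zero")) {
  missing <- match.arg(missing)
  stopifnot(inherits(system, "scoring_system"))
  total <- 0L
  for (i in seq_len(nrow(system$rules))) {
    v <- system$rules$variable[i]
    x <- record[[v]]
    if (is.null(x) || is.na(x)) {
      if (missing == "strict") {
        stop("missing covariate `", v, "` (strict missing-data policy)",
             call. = FALSE)
      }
      next
    }
    if (as.numeric(x) > system$rules$threshold[i]) {
      total <- total + system$rules$points[i]
    }
  }
  total
}

#' Score every patient in a cohort
#'
#' @param cohort Data frame of patient records.
#' @param system A `scoring_system`.
#' @param missing Missing-covariate policy, as in [score_patient()].
#' @return Integer vector of scores aligned with the cohort rows.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 20, seed = 1))
#' score_cohort(coh, preset_scoring_system())
score_cohort <- function(cohort, system, missing = c("strict", "zero")) {
  missing <- match.arg(missing)
  stopifnot(is.data.frame(cohort), inherits(system, "scoring_system"))
  if (nrow(cohort) == 0L) return(integer(0))
  total <- integer(nrow(cohort))
  for (i in seq_len(nrow(system$rules))) {
    v <- system$rules$variable[i]
    if (is.null(cohort[[v]])) {
      stop("missing covariate column `", v, "`", call. = FALSE)
    }
    x <- as.numeric(cohort[[v]])
    if (anyNA(x)) {
      if (missing == "strict") {
        ids <- if (!is.null(cohort$patient_id)) {
          paste(head(cohort$patient_id[is.na(x)], 5), collapse = ", ")
        } else {
          paste("rows", paste(head(which(is.na(x)), 5), collapse = ", "))
        }
        stop("missing `", v, "` for patient(s): ", ids,
             " (strict missing-data policy)", call. = FALSE)
      }
      x[is.na(x)] <- -Inf
    }
    total <- total + system$rules$points[i] * as.integer(x > system$rules$threshold[i])
  }
  total
}

#' Serialize a scoring system to JSON
#'
#' @param system A `scoring_system`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
#' @seealso [read_scoring_system()]
write_scoring_system <- function(system, path) {
  stopifnot(inherits(system, "scoring_system"))
  jsonlite::write_json(
    list(rules = system$rules, max_total = system$max_total),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a scoring system from JSON
#'
#' @param path File written by [write_scoring_system()].
#' @return A `scoring_system` scoring every record identically to the
#'   one serialized.
#' @export
read_scoring_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- as.data.frame(obj$rules, stringsAsFactors = FALSE)
  rules$points <- as.integer(rules$points)
  rules$threshold <- as.numeric(rules$threshold)
  new_scoring_system(rules)
}

#' @export
print.scoring_system <- function(x, ...) {
  cat("<scoring_system>", nrow(x$rules), "rules, max total",
      x$max_total, "\n")
  print(x$rules)
  invisible(x)
}
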