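# Boosted-regression-tree stage: fit a gradient-boosted classifier on a
# cohort and expose the two summaries the score construction consumes,
# split-gain relative influence and partial dependence.

#' Boosted-tree hyperparameters
#'
#' Standard gradient-boosting settings for a rare binary outcome:
#' binomial-deviance loss, shallow trees, mild shrinkage and row
#' subsampling.
#'
#' @param n_trees Number of boosting iterations (default 500).
#' @param max_interaction_depth Maximum tree depth (default 3).
#' @param learning_rate Shrinkage per iteration (default 0.05).
#' @param subsample_fraction Fraction of rows sampled per tree, in (0, 1]
#'   (default 0.75).
#' @param seed Integer seed controlling the subsampling stream; fits are
#'   deterministic given the seed.
#' @return An object of class `brt_hyperparams`.
#' @export
#' @examples
#' brt_hyperparams(n_trees = 100)
brt_hyperparams <- function(n_trees = 500, max_interaction_depth = 3,
                            learning_rate = 0.05, subsample_fraction = 0.75,
                            seed = 1L) {
  n_trees <- assert_count(n_trees, "n_trees")
  max_interaction_depth <- assert_count(max_interaction_depth,
                                        "max_interaction_depth")
  assert_scalar_number(learning_rate, "learning_rate", 0, Inf,
                       strict_lower = TRUE)
  assert_scalar_number(subsample_fraction, "subsample_fraction", 0, 1,
                       strict_lower = TRUE)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_trees = n_trees, max_interaction_depth = max_interaction_depth,
         learning_rate = learning_rate,
         subsample_fraction = subsample_fraction, seed = seed),
    class = "brt_hyperparams"
  )
}

# Encode the covariate block as a numeric matrix. Clinical stage and the
# boolean flags are ordinal/0-1 in substance, so integer codes are adequate.
encode_covariates <- function(data, covariates) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop("schema error: cohort lacks covariate(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (v == "clinical_stage") x <- match(x, c("T1", "T2", "T3"))
    if (is.logical(x)) x <- as.integer(x)
    if (!is.numeric(x)) {
      stop(sprintf("schema error: covariate `%s` is not numeric and has no ",
                   v), "known encoding", call. = FALSE)
    }
    as.numeric(x)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Fit a boosted-regression-tree model to a cohort
#'
#' Gradient boosting with binomial-deviance loss on a binary outcome
#' (xgboost backend). Refitting with identical inputs and seed yields
#' identical predictions.
#'
#' @param cohort Data frame of patient records.
#' @param outcome Name of the binary outcome column (default `"vte_90d"`).
#' @param covariates Character vector of training covariates; defaults to
#'   the full patient covariate set (`MODEL_COVARIATES`).
#' @param hyperparams A [brt_hyperparams()].
#' @return An object of class `brt_model` with a `predict()` method
#'   returning event probabilities in \[0, 1\].
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 400, seed = 1))
#' fit <- fit_brt(coh, hyperparams = brt_hyperparams(n_trees = 50))
#' head(predict(fit, coh))
fit_brt <- function(cohort, outcome = "vte_90d",
                    covariates = MODEL_COVARIATES,
                    hyperparams = brt_hyperparams()) {
  stopifnot(inherits(hyperparams, "brt_hyperparams"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("`cohort` must be a non-empty data frame", call. = FALSE)
  }
  if (!outcome %in% names(cohort)) {
    stop("schema error: outcome column `", outcome, "` not found",
         call. = FALSE)
  }
  x <- encode_covariates(cohort, covariates)
  y <- check_binary_labels(cohort[[outcome]], require_both = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: `", outcome, "` has a single class",
         call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(
    objective = "binary:logistic",
    max_depth = hyperparams$max_interaction_depth,
    eta = hyperparams$learning_rate,
    subsample = hyperparams$subsample_fraction,
    seed = hyperparams$seed,
    nthread = 1
  )
  booster <- xgboost::xgb.train(params, dtrain,
                                nrounds = hyperparams$n_trees, verbose = 0)
  structure(
    list(booster = booster, feature_names = covariates,
         hyperparams = hyperparams, outcome = outcome, train_matrix = x),
    class = "brt_model"
  )
}

#' @export
predict.brt_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else
    encode_covariates(newdata, object$feature_names)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  stopifnot(all(p >= 0), all(p <= 1))
  as.numeric(p)
}

#' @export
print.brt_model <- function(x, ...) {
  cat("<brt_model>", length(x$feature_names), "covariates,",
      x$hyperparams$n_trees, "trees, depth",
      x$hyperparams$max_interaction_depth, "\n")
  invisible(x)
}

#' Relative importance (relative influence) of model variables
#'
#' Split-gain relative influence in the classical boosted-tree sense: the
#' total loss reduction attributed to splits on each variable across the
#' ensemble, normalised so that the importances of all training variables
#' sum to 100.
#'
#' @param model A fitted [fit_brt()] model.
#' @return A data frame of class `importance_table` with columns
#'   `variable` and `relative_importance`, sorted decreasing. Variables
#'   the ensemble never split on appear with importance 0.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 600, seed = 2))
#' fit <- fit_brt(coh, hyperparams = brt_hyperparams(n_trees = 60))
#' head(relative_importance(fit), 3)
relative_importance <- function(model) {
  if (!inherits(model, "brt_model")) {
    stop("`model` must be a fitted brt_model", call. = FALSE)
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  if (is.null(imp) || nrow(imp) == 0L) {
    stop("model contains no splits; relative importance is undefined",
         call. = FALSE)
  }
  gain <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  gain[imp$Feature] <- imp$Gain
  gain <- 100 * gain / sum(gain)
  out <- data.frame(
    variable = names(gain), relative_importance = unname(gain),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$relative_importance, out$variable), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Partial dependence of the model on one covariate
#'
#' Standard partial dependence: for each grid value, the model's mean
#' predicted probability over the training records with the chosen
#' covariate clamped to that value.
#'
#' @param model A fitted [fit_brt()] model.
#' @param variable Name of a training covariate.
#' @param grid Optional sorted numeric vector of covariate values; by
#'   default 50 equally spaced points between the 1st and 99th percentile
#'   of the training values (deduplicated for discrete covariates).
#' @return A data frame of class `pd_curve` with columns `grid` and
#'   `effect`, plus a `"variable"` attribute.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 600, seed = 2))
#' fit <- fit_brt(coh, hyperparams = brt_hyperparams(n_trees = 60))
#' pd <- partial_dependence(fit, "psa")
#' plot(pd$grid, pd$effect, type = "l")
partial_dependence <- function(model, variable, grid = NULL) {
  if (!inherits(model, "brt_model")) {
    stop("`model` must be a fitted brt_model", call. = FALSE)
  }
  if (!variable %in% model$feature_names) {
    stop("schema error: `", variable, "` was not a training covariate",
         call. = FALSE)
  }
  xv <- model$train_matrix[, variable]
  if (is.null(grid)) {
    qs <- quantile(xv, c(0.01, 0.99), names = FALSE, type = 7)
    grid <- unique(seq(qs[1], qs[2], length.out = 50))
  }
  if (!is.numeric(grid) || length(grid) == 0L || anyNA(grid)) {
    stop("`grid` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  grid <- as.numeric(grid)
  x <- model$train_matrix
  effect <- vapply(grid, function(g) {
    x[, variable] <- g
    mean(predict(model, x))
  }, numeric(1))
  out <- data.frame(grid = grid, effect = effect)
  attr(out, "variable") <- variable
  class(out) <- c("pd_curve", "data.frame")
  out
}
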