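# Cohort CSV schema and reader/writer, run configuration, the
# end-to-end pipeline driver, and report rendering.

#' The cohort CSV schema
#'
#' Column order and types of the patient-level cohort table. Booleans
#' are stored as 0/1, missing values as empty fields, clinical stage as
#' T1/T2/T3 strings.
#'
#' @return Data frame with columns `column` and `type`
#'   (`character`/`integer`/`double`/`logical`).
#' @export
#' @examples
#' cohort_schema()
cohort_schema <- function() {
  data.frame(
    column = c("patient_id", "age", "bmi", "psa", "gleason",
               "clinical_stage", "prostate_volume", "operative_time",
               "eplnd", "n_comorbidities", "clotting_disease_count",
               "neurological_disease_count", "mets_score", "prior_vte",
               "duration_first_admission", "n_readmissions",
               "immediate_postop_complication", "prophylaxis", "vte_90d",
               "alive"),
    type = c("character", "integer", "double", "double", "integer",
             "character", "double", "double", "logical", "integer",
             "integer", "integer", "integer", "logical", "integer",
             "integer", "logical", "logical", "logical", "logical"),
    stringsAsFactors = FALSE
  )
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (anyDuplicated(cohort$patient_id)) {
    dup <- cohort$patient_id[duplicated(cohort$patient_id)][1]
    stop("schema error: duplicate patient_id `", dup, "`", call. = FALSE)
  }
  checks <- list(
    bmi = function(x) all(is.na(x) | x > 0),
    psa = function(x) all(is.na(x) | x >= 0),
    gleason = function(x) all(is.na(x) | x %in% 6:10),
    clinical_stage = function(x) all(is.na(x) | x %in% c("T1", "T2", "T3"))
  )
  for (v in c("n_comorbidities", "clotting_disease_count",
              "neurological_disease_count", "mets_score",
              "duration_first_admission", "n_readmissions")) {
    checks[[v]] <- function(x) all(is.na(x) | x >= 0)
  }
  for (v in names(checks)) {
    if (!checks[[v]](cohort[[v]])) {
      stop("schema error: invalid values in column `", v, "`",
           call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Deterministic column order and full-precision float formatting, so
#' identical cohorts always produce byte-identical files. Booleans are
#' written as 0/1, missing values as empty fields.
#'
#' @param cohort Data frame of patient records with the full schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @seealso [read_cohort()]
write_cohort <- function(cohort, path) {
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column, names(cohort))
  if (length(missing_cols)) {
    stop("schema error: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_cohort(cohort)
  cols <- lapply(seq_len(nrow(sch)), function(i) {
    x <- cohort[[sch$column[i]]]
    out <- switch(sch$type[i],
      character = as.character(x),
      integer = as.character(as.integer(x)),
      logical = as.character(as.integer(x)),
      # %.17g round-trips doubles exactly
      double = vapply(as.numeric(x), function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    )
    out[is.na(out)] <- ""
    out
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sch$column
  lines <- c(paste(sch$column, collapse = ","),
             if (nrow(cohort)) apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

coerce_column <- function(x, type, column) {
  x[x == ""] <- NA
  idx_given <- which(!is.na(x))
  out <- switch(type,
    character = x,
    integer = suppressWarnings(as.integer(x)),
    double = suppressWarnings(as.numeric(x)),
    logical = {
      v <- suppressWarnings(as.integer(x))
      v[!is.na(v) & !v %in% c(0L, 1L)] <- NA_integer_
      as.logical(v)
    }
  )
  bad <- idx_given[is.na(out[idx_given])]
  if (length(bad)) {
    stop(sprintf(
      "schema error: cannot coerce value \"%s\" in column `%s`, row %d, to %s",
      x[bad[1]], column, bad[1], type
    ), call. = FALSE)
  }
  out
}

#' Read a cohort from CSV
#'
#' Validates the header against [cohort_schema()], coerces every cell to
#' its schema type with row/column error locations, checks patient-id
#' uniqueness and field invariants, and preserves row order.
#'
#' @param path CSV file written by [write_cohort()] (or any file with
#'   the same schema).
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), sch$column)
  if (length(unknown)) {
    stop("schema error: unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(seq_len(nrow(sch)), function(i) {
    coerce_column(raw[[sch$column[i]]], sch$type[i], sch$column[i])
  })
  names(cols) <- sch$column
  cohort <- as.data.frame(cols, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings: exactly one cohort source (a CSV path
#' or a [cohort_config()] for simulation), boosted-tree hyperparameters,
#' the banding scheme and forced rules, cut-off resampling parameters,
#' and evaluation parameters.
#'
#' @param cohort_source A file path (character) or a [cohort_config()].
#' @param hyperparams A [brt_hyperparams()].
#' @param scheme A [banding_scheme()].
#' @param forced_rules Data frame of [score_rule()] rows appended to the
#'   banded rules; default forces one point for Gleason score above 6,
#'   the literature-motivated rule of the reference system.
#' @param scoring_system Optional fixed `scoring_system`; when given,
#'   the model-fitting and score-building stages are skipped and the
#'   cohort is scored with it directly.
#' @param cutoff_B,cutoff_m,cutoff_p Simulation cut-off parameters
#'   (defaults 10000 resamples of size 5, quantile level 0.025).
#' @param bootstrap_B Resamples for the bootstrap cut-off (default 1000).
#' @param eval_B,eval_level AUC bootstrap parameters (defaults 2000,
#'   0.95).
#' @param holdout_fraction Fraction of the cohort held out from model
#'   fitting for honest discrimination assessment (default 0.3; 0
#'   evaluates on the training data).
#' @param exclude_prophylaxis Restrict the analysis to
#'   prophylaxis-naive patients (default `TRUE`).
#' @param group_variables Variables for the baseline group-comparison
#'   table.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param output_dir Optional directory for intermediate artifacts.
#' @return An object of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(cohort_source = cohort_config(n = 300, seed = 1))
run_config <- function(cohort_source = cohort_config(),
                       hyperparams = brt_hyperparams(),
                       scheme = banding_scheme(),
                       forced_rules = score_rule("gleason", 6, 1),
                       scoring_system = NULL,
                       cutoff_B = 10000L, cutoff_m = 5L, cutoff_p = 0.025,
                       bootstrap_B = 1000L, eval_B = 2000L,
                       eval_level = 0.95, holdout_fraction = 0.3,
                       exclude_prophylaxis = TRUE,
                       group_variables = c("age", "bmi", "psa",
                                           "duration_first_admission",
                                           "n_readmissions", "alive"),
                       seed = 1L, output_dir = NULL) {
  if (!(is.character(cohort_source) && length(cohort_source) == 1L) &&
      !inherits(cohort_source, "cohort_config")) {
    stop("`cohort_source` must be a file path or a cohort_config",
         call. = FALSE)
  }
  stopifnot(inherits(hyperparams, "brt_hyperparams"),
            inherits(scheme, "banding_scheme"))
  if (!is.null(scoring_system)) {
    stopifnot(inherits(scoring_system, "scoring_system"))
  }
  assert_scalar_number(holdout_fraction, "holdout_fraction", 0, 0.9)
  structure(
    list(cohort_source = cohort_source, hyperparams = hyperparams,
         scheme = scheme, forced_rules = forced_rules,
         scoring_system = scoring_system,
         cutoff_B = assert_count(cutoff_B, "cutoff_B"),
         cutoff_m = assert_count(cutoff_m, "cutoff_m"),
         cutoff_p = assert_scalar_number(cutoff_p, "cutoff_p", 0, 1,
                                         strict_lower = TRUE,
                                         strict_upper = TRUE),
         bootstrap_B = assert_count(bootstrap_B, "bootstrap_B"),
         eval_B = assert_count(eval_B, "eval_B", min = 100L),
         eval_level = eval_level,
         holdout_fraction = holdout_fraction,
         exclude_prophylaxis = isTRUE(exclude_prophylaxis),
         group_variables = group_variables,
         seed = assert_count(seed, "seed", min = 0L),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full risk-score pipeline
#'
#' Executes the whole analysis: simulate or load the cohort, restrict to
#' the prophylaxis-naive subgroup, fit the boosted-tree model on a
#' training split, extract relative importances and partial-dependence
#' curves, build the scoring system (banding plus forced rules), score
#' the cohort, estimate cut-offs by all four methods (simulation,
#' calibrated, Youden, bootstrap), assess discrimination (ROC/AUC with
#' bootstrap CI, on the held-out split when configured) and confusion
#' metrics at the calibrated cut-off, and compare baseline variables
#' between outcome groups. Fully reproducible from the configuration.
#'
#' @param config A [run_config()].
#' @return An object of class `analysis_report`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(cohort_source = cohort_config(n = 600, seed = 9),
#'                   hyperparams = brt_hyperparams(n_trees = 60),
#'                   cutoff_B = 2000, bootstrap_B = 200, eval_B = 200)
#' rep <- run_pipeline(cfg)
#' rep$cutoffs
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- list(split = config$seed, fit = config$seed + 1L,
                cutoff = config$seed + 2L, bootstrap = config$seed + 3L,
                eval = config$seed + 4L)

  cohort <- stage("cohort", {
    if (is.character(config$cohort_source)) read_cohort(config$cohort_source)
    else generate_cohort(config$cohort_source)
  })
  analysis <- if (config$exclude_prophylaxis) {
    cohort[!cohort$prophylaxis, , drop = FALSE]
  } else {
    cohort
  }
  if (nrow(analysis) == 0L) {
    stop("pipeline stage `cohort` failed: no analysis patients left",
         call. = FALSE)
  }

  # Train/holdout split for honest discrimination assessment.
  idx_hold <- with_seed(seeds$split, {
    if (config$holdout_fraction > 0) {
      sort(sample.int(nrow(analysis),
                      floor(config$holdout_fraction * nrow(analysis))))
    } else {
      integer(0)
    }
  })
  train <- if (length(idx_hold)) analysis[-idx_hold, , drop = FALSE]
           else analysis
  holdout <- if (length(idx_hold)) analysis[idx_hold, , drop = FALSE]
             else analysis

  if (is.null(config$scoring_system)) {
    fit <- stage("fit", {
      hp <- config$hyperparams
      hp$seed <- seeds$fit
      fit_brt(train, hyperparams = hp)
    })
    importance <- stage("importance", relative_importance(fit))
    curves <- stage("partial_dependence", {
      pts <- band_points(importance$relative_importance, config$scheme)
      vars <- importance$variable[!is.na(pts)]
      setNames(lapply(vars, function(v) partial_dependence(fit, v)), vars)
    })
    system <- stage("build_score", {
      # Fallback for flat curves: the variable's rounded training median.
      fallback <- vapply(colnames(fit$train_matrix), function(v) {
        round(median(fit$train_matrix[, v]))
      }, numeric(1))
      build_scoring_system(importance, curves, scheme = config$scheme,
                           forced_rules = config$forced_rules,
                           fallback_thresholds = fallback)
    })
  } else {
    fit <- NULL
    importance <- NULL
    curves <- NULL
    system <- config$scoring_system
  }

  scores <- stage("score", score_cohort(analysis, system))
  labels <- as.integer(analysis$vte_90d)
  positive_scores <- scores[labels == 1L]
  if (length(positive_scores) == 0L) {
    stop("cannot calibrate cut-off: the analysis cohort contains no ",
         "VTE-positive patients", call. = FALSE)
  }

  cutoffs <- stage("cutoff", {
    sim <- simulation_cutoff(positive_scores, B = config$cutoff_B,
                             m = config$cutoff_m,
                             qspec = quantile_spec(p = config$cutoff_p),
                             seed = seeds$cutoff)
    cal <- calibrate_cutoff(sim, positive_scores)
    you <- youden_cutoff(scores, labels)
    boo <- bootstrap_cutoff(scores, labels, B = config$bootstrap_B,
                            seed = seeds$bootstrap)
    list(simulation = sim, calibrated = cal, youden = you, bootstrap = boo)
  })

  # Discrimination on the held-out split: the fitted model's predictions
  # (the model ROC) and the integer score (the deliverable's ROC). Both
  # are NULL, marked "not computed", if the holdout lacks an outcome class.
  hl <- as.integer(holdout$vte_90d)
  holdout_ok <- length(unique(hl)) == 2L
  roc <- stage("evaluate", {
    if (!holdout_ok) NULL
    else {
      pred <- if (!is.null(fit)) predict(fit, holdout)
              else score_cohort(holdout, system)
      roc_summary(pred, hl, B = config$eval_B, level = config$eval_level,
                  seed = seeds$eval)
    }
  })
  score_roc <- stage("evaluate", {
    if (!holdout_ok) NULL
    else roc_summary(score_cohort(holdout, system), hl,
                     B = config$eval_B, level = config$eval_level,
                     seed = seeds$eval)
  })
  confusion <- stage("evaluate", {
    confusion_metrics(scores, labels, cutoffs$calibrated$value)
  })
  groups <- stage("compare_groups", {
    vars <- intersect(config$group_variables, names(analysis))
    setNames(lapply(vars, function(v) compare_groups(analysis, v)), vars)
  })

  report <- structure(
    list(
      cohort = cohort, analysis_n = nrow(analysis),
      n_events = sum(labels), importance = importance, curves = curves,
      scoring_system = system, scores = data.frame(
        patient_id = analysis$patient_id, score = scores,
        vte_90d = labels, stringsAsFactors = FALSE
      ),
      cutoffs = cutoff_table(cutoffs), roc = roc, score_roc = score_roc,
      confusion = confusion,
      group_comparisons = groups,
      provenance = list(
        config_hash = rlang::hash(config[setdiff(names(config),
                                                 "output_dir")]),
        seed = config$seed, stage_seeds = seeds,
        package_version = as.character(utils::packageVersion("vterisk")),
        r_version = R.version.string,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "analysis_report"
  )
  if (!is.null(config$output_dir)) {
    write_artifacts(report, config$output_dir)
  }
  report
}

write_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  if (!is.null(report$importance)) {
    write.csv(report$importance, file.path(dir, "importance.csv"),
              row.names = FALSE)
  }
  write_scoring_system(report$scoring_system, file.path(dir, "rules.json"))
  write.csv(report$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(report$cutoffs, file.path(dir, "cutoffs.csv"),
            row.names = FALSE)
  write_report(report, dir)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  analysis cohort:", x$analysis_n, "patients,", x$n_events,
      "VTE events\n")
  cat("  scoring system:", nrow(x$scoring_system$rules),
      "rules, max total", x$scoring_system$max_total, "\n")
  cat("  cut-offs:\n")
  print(x$cutoffs)
  if (!is.null(x$roc)) {
    cat(sprintf("  held-out model AUC %.3f (CI %.3f-%.3f)\n", x$roc$auc,
                x$roc$ci_low, x$roc$ci_high))
  }
  if (!is.null(x$score_roc)) {
    cat(sprintf("  held-out score AUC %.3f (CI %.3f-%.3f)\n",
                x$score_roc$auc, x$score_roc$ci_low, x$score_roc$ci_high))
  }
  invisible(x)
}

roc_to_list <- function(roc) {
  if (is.null(roc)) return(NULL)
  list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
       ci_method = roc$ci_method, B = roc$B, level = roc$level,
       seed = roc$seed, points = roc$points)
}

report_to_list <- function(report) {
  list(
    analysis_n = report$analysis_n, n_events = report$n_events,
    importance = report$importance,
    scoring_system = list(rules = report$scoring_system$rules,
                          max_total = report$scoring_system$max_total),
    scores = report$scores, cutoffs = report$cutoffs,
    roc = roc_to_list(report$roc),
    score_roc = roc_to_list(report$score_roc),
    confusion = unclass(report$confusion),
    group_comparisons = lapply(report$group_comparisons, function(g) {
      list(variable = g$variable, test = g$test,
           statistic = g$statistic, p_value = g$p_value)
    }),
    provenance = report$provenance
  )
}

md_table <- function(df, digits = 4) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) trimws(format(round(col, digits)))
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Write an analysis report to disk
#'
#' Renders the report twice: `report.json` (machine-readable, lossless
#' round trip of every numeric artifact) and `report.md` (human-readable
#' markdown with the scoring-rule, cut-off and group-comparison tables
#' and a provenance block). Stages that were not computed are rendered
#' with an explicit "not computed" marker.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  lines <- c(
    "# VTE risk-score analysis report", "",
    sprintf("Analysis cohort: %d patients, %d VTE events (%.1f%%).",
            report$analysis_n, report$n_events,
            100 * report$n_events / report$analysis_n), "",
    "## Relative importance", ""
  )
  lines <- c(lines, if (is.null(report$importance)) {
    "not computed (a fixed scoring system was supplied)"
  } else {
    md_table(report$importance)
  })
  lines <- c(lines, "", "## Scoring system", "",
             md_table(report$scoring_system$rules), "",
             sprintf("Maximum total score: %d.",
                     report$scoring_system$max_total),
             "", "## Cut-off comparison", "", md_table(report$cutoffs), "")
  roc_line <- function(roc, what) {
    if (is.null(roc)) {
      sprintf("%s: not computed (held-out split lacked both outcome classes)",
              what)
    } else {
      sprintf("%s: AUC %.3f (%d%% CI %.3f-%.3f; %s, B = %d).", what,
              roc$auc, round(100 * roc$level), roc$ci_low, roc$ci_high,
              roc$ci_method, roc$B)
    }
  }
  lines <- c(lines, "## Discrimination (held-out)", "",
             roc_line(report$roc, "Fitted model"), "",
             roc_line(report$score_roc, "Integer risk score"), "")
  cm <- report$confusion
  lines <- c(lines, "## Confusion metrics at the calibrated cut-off", "",
             md_table(data.frame(
               cutoff = cm$cutoff, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, sensitivity = cm$sensitivity,
               specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv
             )), "")
  if (length(report$group_comparisons)) {
    gc_df <- do.call(rbind, lapply(report$group_comparisons, function(g) {
      data.frame(variable = g$variable, test = g$test,
                 p_value = g$p_value, stringsAsFactors = FALSE)
    }))
    lines <- c(lines, "## Group comparisons (VTE vs non-VTE)", "",
               md_table(gc_df), "")
  }
  pv <- report$provenance
  lines <- c(lines, "## Provenance", "",
             sprintf("- config hash: %s", pv$config_hash),
             sprintf("- master seed: %d", pv$seed),
             sprintf("- package version: %s", pv$package_version),
             sprintf("- %s", pv$r_version),
             sprintf("- generated: %s UTC", pv$timestamp), "")
  md_path <- file.path(dir, "report.md")
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}
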