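# Shared fixtures, all built in code.

# The six observed risk scores of the VTE-positive patients used as the
# worked example throughout the cut-off module.
vte_scores <- c(5, 6, 9, 14, 15, 15)

# Published relative-importance column for the eight banded variables.
reference_importances <- data.frame(
  variable = c("duration_first_admission", "psa", "bmi", "age",
               "clotting_disease_count", "n_comorbidities", "mets_score",
               "neurological_disease_count"),
  relative_importance = c(30.1300915, 29.9357324, 24.3406184, 5.2599722,
                          4.05020792, 1.91640052, 1.23960532, 1.17630012),
  stringsAsFactors = FALSE
)

# Step partial-dependence curve: low effect up to `jump_after`, high after.
step_curve <- function(jump_after, grid = 0:15, low = 0.1, high = 0.6) {
  data.frame(grid = grid, effect = ifelse(grid > jump_after, high, low))
}

# One full-schema patient record; override any field by name.
make_record <- function(..., id = "P00001") {
  rec <- list(
    patient_id = id, age = 60L, bmi = 25, psa = 5, gleason = 6L,
    clinical_stage = "T2", prostate_volume = 40, operative_time = 180,
    eplnd = TRUE, n_comorbidities = 1L, clotting_disease_count = 0L,
    neurological_disease_count = 0L, mets_score = 2L, prior_vte = FALSE,
    duration_first_admission = 3L, n_readmissions = 0L,
    immediate_postop_complication = FALSE, prophylaxis = FALSE,
    vte_90d = FALSE, alive = TRUE
  )
  rec[names(list(...))] <- list(...)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Record meeting every condition of the preset scoring system (score 24).
all_conditions_record <- function(id = "P99999") {
  make_record(
    id = id, duration_first_admission = 10L, psa = 12, bmi = 31,
    age = 66L, clotting_disease_count = 1L, n_comorbidities = 4L,
    mets_score = 4L, neurological_disease_count = 1L, gleason = 7L
  )
}

# Small cohort whose VTE-positive patients score exactly 5, 6, 9, 14, 15,
# 15 under the preset system, embedded among low-scoring negatives.
make_reference_cohort <- function(n_neg = 30) {
  pos <- rbind(
    make_record(duration_first_admission = 9L),
    make_record(duration_first_admission = 9L, gleason = 7L),
    make_record(duration_first_admission = 9L, psa = 12),
    make_record(duration_first_admission = 9L, psa = 12, bmi = 31,
                gleason = 7L),
    make_record(duration_first_admission = 9L, psa = 12, bmi = 31,
                age = 66L),
    make_record(duration_first_admission = 9L, psa = 12, bmi = 31,
                clotting_disease_count = 1L)
  )
  pos$vte_90d <- TRUE
  neg <- do.call(rbind, lapply(seq_len(n_neg), function(i) make_record()))
  coh <- rbind(pos, neg)
  coh$patient_id <- sprintf("P%05d", seq_len(nrow(coh)))
  coh
}

# Cohort with a perfectly learnable single-split signal on one covariate.
make_threshold_cohort <- function(n = 800, variable = "psa",
                                  threshold = 10, seed = 1) {
  coh <- generate_cohort(cohort_config(n = n, effects = numeric(0),
                                       seed = seed))
  coh$vte_90d <- coh[[variable]] > threshold
  coh
}
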