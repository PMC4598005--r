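# Shared fixtures and independent oracles used across the test files.

surv_df <- function(time, event, ...) {
  tibble::tibble(observed_time = time, event_observed = as.logical(event), ...)
}

# Brute-force split oracle: enumerate every (feature, midpoint) pair through
# the scalar statistic and return the maximal |F| (and the argmax under the
# same tie-break as the implementation: lower name, then lower cut).
brute_best_split <- function(data, features) {
  best <- NULL
  for (f in sort(features)) {
    xs <- sort(unique(data[[f]]))
    if (length(xs) < 2) next
    for (cut in (xs[-1] + xs[-length(xs)]) / 2) {
      F <- logrank_statistic(data, f, cut)
      if (is.na(F)) next
      if (is.null(best) || abs(F) > best$absF + 1e-12) {
        best <- list(feature = f, cut = cut, absF = abs(F), F = F)
      }
    }
  }
  best
}

# Walk a fitted single tree and check that every internal node's split
# reproduces the brute-force maximum over all features (requires mtry = p).
check_tree_structure <- function(fit, data, features) {
  tr <- fit$trees[[1]]
  recurse <- function(node, rows) {
    col <- tr$split_col[node + 1]
    if (col < 0) return(invisible(NULL))
    sub <- data[rows, , drop = FALSE]
    oracle <- brute_best_split(sub, features)
    expect_equal(features[col + 1], oracle$feature)
    expect_equal(tr$split_val[node + 1], oracle$cut, tolerance = 1e-12)
    left <- rows[sub[[features[col + 1]]] <= tr$split_val[node + 1]]
    right <- setdiff(rows, left)
    recurse(tr$left[node + 1], left)
    recurse(tr$right[node + 1], right)
  }
  recurse(0L, seq_len(nrow(data)))
}

# Exhaustive pairwise AUC oracle.
brute_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  grid <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(grid)
}

total_ss <- function(X) sum(scale(X, scale = FALSE)^2)

# A tiny hand-made encounter fixture: one patient, controllable encounters.
manual_cohort <- function(encounters, index_date = as.Date("2013-06-01"),
                          n_extra_patients = 0) {
  patients <- tibble::tibble(
    patient_id = c("P1", if (n_extra_patients > 0)
      sprintf("PX%d", seq_len(n_extra_patients))),
    age_group = "50-65", gender = "F", payer = "Medicare",
    income_band = 3L, education_band = 2L, facility_id = "F01")
  index <- tibble::tibble(
    index_id = "IDX1", patient_id = "P1", discharge_date = index_date,
    true_time_to_readmission = 10L, event_within_30d = TRUE,
    observed_time = 10L, event_observed = TRUE,
    true_daily_hazard = 0.05, archetype = 0L)
  list(patients = patients, encounters = encounters,
       index_discharges = index)
}

enc_row <- function(id, days_before_index, type = "E", los = 0,
                    index_date = as.Date("2013-06-01"), flags = "",
                    labs = 0L, meds = 0L, rad = 0L) {
  tibble::tibble(
    encounter_id = id, patient_id = "P1", encounter_type = type,
    admit_date = index_date - days_before_index - los,
    discharge_date = index_date - days_before_index,
    chronic_flags = flags, n_labs = labs, n_meds = meds,
    n_radiology = rad, primary_dx = "dx001", secondary_dx = "dx002")
}
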