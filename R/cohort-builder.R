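#' Aggregate 12-month look-back features per index discharge
#'
#' Computes one feature row per index discharge from the encounters whose
#' discharge date falls in the half-open look-back window
#' `(index_date - lookback_days, index_date]`, excluding the index encounter
#' itself. No feature reads post-index data.
#'
#' Features follow the standard encounter-history groups: visit counts per
#' encounter type (E/O/I/P/R), accumulated inpatient length of stay, count of
#' distinct chronic conditions plus per-condition encounter counts, total and
#' non-redundant lab / medication / radiology counts (non-redundant = number
#' of distinct encounter occasions with at least one such order), and
#' patient-level demographics (age-group index, gender, payer indicators,
#' income and education bands). Any additional numeric patient-level column
#' (e.g. planted signal/noise covariates from the generator) is passed
#' through as a feature.
#'
#' @param encounters Encounter table (see [generate_cohort()]).
#' @param index Index-discharge table with `index_id`, `patient_id`,
#'   `discharge_date`.
#' @param patients Patient table with demographics.
#' @param lookback_days Length of the look-back window (days).
#' @return A tibble with `index_id`, `patient_id` and numeric feature
#'   columns.
#' @export
aggregate_features <- function(encounters, index, patients,
                               lookback_days = 365) {
  missing_pat <- setdiff(index$patient_id, patients$patient_id)
  if (length(missing_pat)) {
    abort(sprintf("index discharge without a matching patient: %s",
                  missing_pat[1]))
  }

  skeleton <- index |>
    select("index_id", "patient_id", index_date = "discharge_date")

  window <- encounters |>
    inner_join(skeleton, by = "patient_id",
               relationship = "many-to-many") |>
    filter(.data$discharge_date > .data$index_date - lookback_days,
           .data$discharge_date <= .data$index_date,
           .data$encounter_id != .data$index_id)

  type_counts <- window |>
    count(.data$index_id, .data$encounter_type) |>
    tidyr::pivot_wider(names_from = "encounter_type", values_from = "n",
                       names_prefix = "count_", values_fill = 0L)
  for (tp in encounter_type_levels()) {
    nm <- paste0("count_", tp)
    if (!nm %in% names(type_counts)) type_counts[[nm]] <- 0L
  }

  util <- window |>
    group_by(.data$index_id) |>
    summarise(
      los_total = sum(as.integer(.data$discharge_date - .data$admit_date)
                      [.data$encounter_type == "I"]),
      labs_total = sum(.data$n_labs),
      labs_nonredundant = sum(.data$n_labs > 0),
      meds_total = sum(.data$n_meds),
      meds_nonredundant = sum(.data$n_meds > 0),
      radiology_total = sum(.data$n_radiology),
      radiology_nonredundant = sum(.data$n_radiology > 0),
      .groups = "drop")

  conditions <- chronic_catalogue()
  flags <- window |>
    filter(.data$chronic_flags != "") |>
    select("index_id", "chronic_flags") |>
    tidyr::separate_rows("chronic_flags", sep = ";")
  cond_counts <- flags |>
    count(.data$index_id, .data$chronic_flags) |>
    tidyr::pivot_wider(names_from = "chronic_flags", values_from = "n",
                       names_prefix = "chronic_", values_fill = 0L)
  for (cc in conditions) {
    nm <- paste0("chronic_", cc)
    if (!nm %in% names(cond_counts)) cond_counts[[nm]] <- 0L
  }
  cond_counts <- cond_counts |>
    select("index_id", all_of(paste0("chronic_", conditions)))
  chronic_distinct <- flags |>
    distinct(.data$index_id, .data$chronic_flags) |>
    count(.data$index_id, name = "chronic_count")

  demo <- patients |>
    mutate(age_group_idx = match(.data$age_group, age_group_levels()) - 1L,
           is_female = as.integer(.data$gender == "F")) |>
    select(-"age_group", -"gender", -"facility_id")
  payer_levels <- sort(unique(demo$payer))
  for (pl in payer_levels) {
    demo[[paste0("payer_", pl)]] <- as.integer(demo$payer == pl)
  }
  demo$payer <- NULL

  out <- skeleton |>
    left_join(type_counts, by = "index_id") |>
    left_join(util, by = "index_id") |>
    left_join(cond_counts, by = "index_id") |>
    left_join(chronic_distinct, by = "index_id") |>
    left_join(demo, by = "patient_id") |>
    select(-"index_date") |>
    mutate(across(where(is.numeric), ~ tidyr::replace_na(.x, 0))) |>
    mutate(across(where(is.integer), as.numeric))
  out
}

#' Names of the feature columns of an aggregated feature table
#' @param features Output of [aggregate_features()].
#' @return Character vector of feature column names (ids excluded).
#' @export
feature_columns <- function(features) {
  reserved <- c("index_id", "patient_id", "discharge_date", "observed_time",
                "event_observed", "event_within_30d", "archetype",
                "true_time_to_readmission", "true_daily_hazard",
                "subgroup", "split")
  setdiff(names(features)[vapply(features, is.numeric, logical(1))], reserved)
}

#' Variance-based feature filtering
#'
#' Removes constant (zero-variance) features, then ranks the remainder by the
#' sample variance of their min-max-scaled values (so the ranking is free of
#' measurement scale) and keeps the `n_keep` largest. Ties are broken by
#' feature name so the result is deterministic.
#'
#' @param features Feature table from [aggregate_features()].
#' @param n_keep Number of features to retain.
#' @param cols Candidate feature columns (default all feature columns).
#' @return Character vector of retained feature names, ordered by decreasing
#'   scaled variance.
#' @export
variance_filter <- function(features, n_keep, cols = feature_columns(features)) {
  if (!is.numeric(n_keep) || n_keep <= 0) {
    abort("`n_keep` must be a positive count.")
  }
  v <- vapply(cols, function(nm) {
    x <- features[[nm]]
    r <- range(x)
    if (!is.finite(r[1]) || r[1] == r[2]) return(NA_real_)
    var((x - r[1]) / (r[2] - r[1]))
  }, numeric(1))
  keep <- tibble(feature = cols, scaled_var = v) |>
    filter(!is.na(.data$scaled_var), .data$scaled_var > 0) |>
    arrange(desc(.data$scaled_var), .data$feature)
  head(keep$feature, n_keep)
}

#' Assign the four chronic-disease x inpatient-history sub-cohorts
#'
#' Partitions index discharges into `CD+IP`, `CD-only`, `IP-only` and
#' `neither` by the presence of at least one chronic-disease diagnosis and at
#' least one inpatient admission in the look-back window.
#'
#' @param features Feature table containing `chronic_count` and `count_I`.
#' @return Tibble with `index_id` and a `subcohort` factor.
#' @export
assign_subcohort <- function(features) {
  need <- c("chronic_count", "count_I")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    abort(sprintf("missing required feature(s): %s",
                  paste(miss, collapse = ", ")))
  }
  features |>
    transmute(.data$index_id,
              subcohort = factor(
                case_when(
                  .data$chronic_count >= 1 & .data$count_I >= 1 ~ "CD+IP",
                  .data$chronic_count >= 1 ~ "CD-only",
                  .data$count_I >= 1 ~ "IP-only",
                  TRUE ~ "neither"),
                levels = subcohort_levels()))
}

#' @rdname assign_subcohort
#' @export
subcohort_levels <- function() c("CD+IP", "CD-only", "IP-only", "neither")

#' Facility-balanced retrospective split
#'
#' Assigns whole facilities to two subgroups by a greedy pass over facilities
#' in decreasing volume, placing each facility in the subgroup that minimizes
#' the maximum over calendar months of the absolute inpatient-volume
#' difference, with the absolute readmission-rate difference as tie-breaker.
#' Subgroup 1 rows are then split into training and calibration cohorts by a
#' patient-level random draw under `seed`; subgroup 2 is the blind test set.
#' The split is a function of facility, month and the seed only - never of an
#' individual row's outcome.
#'
#' @param index Index-discharge table (must contain `index_id`, `patient_id`,
#'   `discharge_date`, `event_within_30d`).
#' @param patients Patient table mapping `patient_id` to `facility_id`.
#' @param train_fraction Fraction of subgroup-1 patients assigned to
#'   training (the rest calibrate).
#' @param seed Seed for the patient-level draw.
#' @return Tibble `index_id`, `patient_id`, `facility_id`, `subgroup`
#'   (1 or 2), `split` (`train` / `calibration` / `blind_test`).
#' @export
facility_balanced_split <- function(index, patients, train_fraction = 0.7,
                                    seed = 1) {
  rows <- index |>
    left_join(select(patients, "patient_id", "facility_id"),
              by = "patient_id") |>
    mutate(month = format(.data$discharge_date, "%Y-%m"))
  facilities <- sort(unique(rows$facility_id))
  if (length(facilities) < 2) {
    abort("at least two facilities are required to form facility-disjoint subgroups.")
  }

  monthly <- rows |>
    count(.data$facility_id, .data$month, name = "volume") |>
    left_join(rows |>
                group_by(.data$facility_id, .data$month) |>
                summarise(events = sum(.data$event_within_30d),
                          .groups = "drop"),
              by = c("facility_id", "month"))
  months <- sort(unique(monthly$month))
  vol_mat <- matrix(0, nrow = length(facilities), ncol = length(months),
                    dimnames = list(facilities, months))
  ev_mat <- vol_mat
  for (i in seq_len(nrow(monthly))) {
    vol_mat[monthly$facility_id[i], monthly$month[i]] <- monthly$volume[i]
    ev_mat[monthly$facility_id[i], monthly$month[i]] <- monthly$events[i]
  }

  ord <- facilities[order(-rowSums(vol_mat), facilities)]
  g1 <- character(0)
  g2 <- character(0)
  objective <- function(grp1, grp2) {
    v1 <- colSums(vol_mat[grp1, , drop = FALSE])
    v2 <- colSums(vol_mat[grp2, , drop = FALSE])
    e1 <- colSums(ev_mat[grp1, , drop = FALSE])
    e2 <- colSums(ev_mat[grp2, , drop = FALSE])
    r1 <- ifelse(v1 > 0, e1 / v1, 0)
    r2 <- ifelse(v2 > 0, e2 / v2, 0)
    c(max(abs(v1 - v2)), max(abs(r1 - r2)))
  }
  for (f in ord) {
    o1 <- objective(c(g1, f), g2)
    o2 <- objective(g1, c(g2, f))
    if (o1[1] < o2[1] || (o1[1] == o2[1] && o1[2] <= o2[2])) {
      g1 <- c(g1, f)
    } else {
      g2 <- c(g2, f)
    }
  }
  if (!length(g2)) {  # degenerate greedy outcome; force disjoint subgroups
    g2 <- g1[length(g1)]
    g1 <- g1[-length(g1)]
  }

  rows$subgroup <- ifelse(rows$facility_id %in% g1, 1L, 2L)
  pat1 <- sort(unique(rows$patient_id[rows$subgroup == 1L]))
  train_pat <- withr::with_seed(
    substream_seed(seed, "train-calibration"),
    sample(pat1, size = round(train_fraction * length(pat1))))
  rows |>
    transmute(.data$index_id, .data$patient_id, .data$facility_id,
              .data$subgroup,
              split = case_when(
                .data$subgroup == 2L ~ "blind_test",
                .data$patient_id %in% train_pat ~ "train",
                TRUE ~ "calibration"))
}
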