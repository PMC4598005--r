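#' Configure the synthetic EHR cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates the statistical structure a 30-day readmission analysis assumes:
#' index inpatient discharges with a 12-month encounter look-back, a
#' discrete-time daily readmission hazard driven by chronic-disease burden,
#' prior inpatient utilization and age, facility membership for cohort
#' splitting, and planted high-risk phenotype archetypes for the clustering
#' stage.
#'
#' The daily readmission hazard of patient \eqn{i} is
#' \deqn{h_i = \mathrm{logit}^{-1}\big(\mathrm{logit}(p_0) + \sum_j \beta_j z_{ij}\big)}
#' where \eqn{p_0} is `baseline_daily_hazard` and the \eqn{\beta_j} are the
#' entries of `effect_log_hr`. Time to readmission is geometric with success
#' probability \eqn{h_i} (day of first readmission, starting at day 1).
#'
#' @param n_patients Number of patients; each contributes one index inpatient
#'   discharge.
#' @param n_facilities Number of hospitals patients are assigned to.
#' @param seed Integer seed; identical config + seed gives identical tables.
#' @param baseline_daily_hazard Daily readmission probability of a reference
#'   patient (all covariates zero). Must be in (0, 1).
#' @param effect_log_hr Named numeric vector of log hazard ratios. The names
#'   `chronic_count`, `prior_inpatient`, `age_group` and `highrisk` refer to
#'   the structural covariates (count of chronic conditions, count of
#'   look-back inpatient stays, age-group index 0-7, planted high-risk
#'   archetype membership). Any other name creates an additional
#'   standard-normal patient-level covariate of that name with the given
#'   log hazard ratio; a value of 0 plants a pure-noise feature.
#' @param n_highrisk_phenotypes Number of planted high-risk archetypes
#'   (distinct age/chronic/utilization profiles) among archetype patients.
#' @param highrisk_fraction Fraction of patients belonging to an archetype.
#' @param horizon_days Administrative follow-up horizon; observed times are
#'   censored there. Must be at least 30 so the 30-day label is observable.
#' @param admin_censor_prob Probability that an index discharge receives an
#'   independent uniform administrative censoring time before the horizon
#'   (default 0: complete 30-day follow-up, the qualification rules remove
#'   deaths and transfers at index).
#'
#' @return A list of class `ehr_config`.
#' @export
#' @examples
#' cfg <- ehr_config(n_patients = 200, seed = 42)
#' cohort <- generate_cohort(cfg)
#' cohort$index_discharges
ehr_config <- function(n_patients = 10000,
                       n_facilities = 10,
                       seed = 1,
                       baseline_daily_hazard = 0.002,
                       effect_log_hr = c(chronic_count = 0.25,
                                         prior_inpatient = 0.30,
                                         age_group = 0.10,
                                         highrisk = 1.5),
                       n_highrisk_phenotypes = 6,
                       highrisk_fraction = 0.15,
                       horizon_days = 60,
                       admin_censor_prob = 0) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 0 ||
      n_patients != floor(n_patients)) {
    abort("`n_patients` must be a single non-negative integer.")
  }
  if (!is.numeric(n_facilities) || n_facilities < 1) {
    abort("`n_facilities` must be a positive integer.")
  }
  if (!is.numeric(baseline_daily_hazard) ||
      baseline_daily_hazard <= 0 || baseline_daily_hazard >= 1) {
    abort("`baseline_daily_hazard` must be a probability strictly in (0, 1).")
  }
  if (!is.numeric(effect_log_hr) ||
      (length(effect_log_hr) > 0 && is.null(names(effect_log_hr)))) {
    abort("`effect_log_hr` must be a named numeric vector.")
  }
  if (n_highrisk_phenotypes < 1) {
    abort("`n_highrisk_phenotypes` must be at least 1.")
  }
  if (horizon_days < 30) {
    abort("`horizon_days` must be at least 30 (the outcome horizon).")
  }
  if (admin_censor_prob < 0 || admin_censor_prob > 1) {
    abort("`admin_censor_prob` must be a probability.")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_facilities = as.integer(n_facilities),
         seed = as.integer(seed),
         baseline_daily_hazard = baseline_daily_hazard,
         effect_log_hr = effect_log_hr,
         n_highrisk_phenotypes = as.integer(n_highrisk_phenotypes),
         highrisk_fraction = highrisk_fraction,
         horizon_days = as.integer(horizon_days),
         admin_censor_prob = admin_censor_prob),
    class = "ehr_config")
}

# Fixed vocabulary of the generator ------------------------------------------

chronic_catalogue <- function() sprintf("c%02d", 1:19)

age_group_levels <- function() {
  c("0", "1-5", "6-12", "13-18", "19-34", "35-49", "50-65", "65+")
}

encounter_type_levels <- function() c("E", "O", "I", "P", "R")

# Archetypes are laid out on a two-axis grid - utilization intensity
# (low / mid / high) by chronic-disease burden (low / high) - so the planted
# cluster structure is essentially two-dimensional and survives the rank-2
# PCA projection the clustering stage applies. Each archetype also carries a
# rotating block of signature chronic conditions for profile identity.
archetype_profile <- function(k) {
  a <- (k - 1) %% 3     # utilization axis
  b <- (k - 1) %/% 3    # burden axis
  n_sig <- 3 + 9 * min(b, 1)
  start <- (3 * (k - 1)) %% 19
  sig <- chronic_catalogue()[(start + seq_len(n_sig) - 1) %% 19 + 1]
  list(signature = sig,
       age_idx = 5 + (k - 1) %% 4,                 # adults through elderly
       util_level = a,
       burden_level = b,
       lab_mult = 1 + 4 * a,
       med_mult = 1 + 4 * b,
       rad_mult = 1 + 4 * a)
}

#' Generate a synthetic patient cohort
#'
#' Draws patients, their 24-month encounter histories and one index inpatient
#' discharge per patient under the configured discrete-time readmission
#' hazard. Index discharges fall in months 13-24 of the calendar so that
#' every index has a complete 12-month look-back. Patients are alive and not
#' transferred at index (the generator never emits such records), and the
#' latent generating hazard is recorded for parameter-recovery tests.
#'
#' @param config An [ehr_config()] object.
#' @return A list of three tibbles: `patients`, `encounters`,
#'   `index_discharges`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "ehr_config")) {
    abort("`config` must be created by `ehr_config()`.")
  }
  n <- config$n_patients
  if (n == 0) {
    return(list(patients = empty_patients(config),
                encounters = empty_encounters(),
                index_discharges = empty_index()))
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

empty_patients <- function(config) {
  extra <- extra_feature_names(config)
  base <- tibble(patient_id = character(), age_group = character(),
                 gender = character(), payer = character(),
                 income_band = integer(), education_band = integer(),
                 facility_id = character())
  for (nm in extra) base[[nm]] <- numeric()
  base
}

empty_encounters <- function() {
  tibble(encounter_id = character(), patient_id = character(),
         encounter_type = character(),
         admit_date = as.Date(character()),
         discharge_date = as.Date(character()),
         chronic_flags = character(), n_labs = integer(), n_meds = integer(),
         n_radiology = integer(), primary_dx = character(),
         secondary_dx = character())
}

empty_index <- function() {
  tibble(index_id = character(), patient_id = character(),
         discharge_date = as.Date(character()),
         true_time_to_readmission = integer(),
         event_within_30d = logical(), observed_time = integer(),
         event_observed = logical(), true_daily_hazard = numeric(),
         archetype = integer())
}

extra_feature_names <- function(config) {
  structural <- c("chronic_count", "prior_inpatient", "age_group", "highrisk")
  setdiff(names(config$effect_log_hr), structural)
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  K <- config$n_highrisk_phenotypes
  calendar_start <- as.Date("2012-01-01")

  # --- patients ------------------------------------------------------------
  patient_id <- sprintf("P%06d", seq_len(n))
  facility_id <- sprintf("F%02d", sample.int(config$n_facilities, n,
                                             replace = TRUE))
  archetype <- ifelse(runif(n) < config$highrisk_fraction,
                      sample.int(K, n, replace = TRUE), 0L)
  profiles <- lapply(seq_len(K), archetype_profile)

  age_idx <- sample(1:8, n, replace = TRUE,
                    prob = c(.02, .03, .04, .04, .18, .22, .27, .20))
  is_arch <- archetype > 0L
  if (any(is_arch)) {
    age_idx[is_arch] <- map_int(archetype[is_arch],
                                ~ profiles[[.x]]$age_idx)
  }
  gender <- sample(c("F", "M"), n, replace = TRUE)
  payer <- sample(c("Commercial", "Medicare", "Medicaid", "Uninsured"), n,
                  replace = TRUE, prob = c(.42, .3, .2, .08))
  income_band <- sample.int(5L, n, replace = TRUE)
  education_band <- sample.int(4L, n, replace = TRUE)

  # chronic conditions: age-driven baseline prevalence; archetypes carry a
  # near-deterministic three-condition signature
  conditions <- chronic_catalogue()
  p_cond <- plogis(-3.8 + 0.28 * age_idx)
  cond_mat <- matrix(runif(n * 19) < p_cond, nrow = n)
  colnames(cond_mat) <- conditions
  if (any(is_arch)) {
    for (k in seq_len(K)) {
      rows <- which(archetype == k)
      if (!length(rows)) next
      sig <- profiles[[k]]$signature
      cond_mat[rows, ] <- matrix(runif(length(rows) * 19) < 0.03,
                                 nrow = length(rows))
      cond_mat[rows, sig] <- matrix(runif(length(rows) * length(sig)) < 0.95,
                                    nrow = length(rows))
    }
  }
  chronic_count <- rowSums(cond_mat)

  extra <- extra_feature_names(config)
  extra_mat <- NULL
  if (length(extra)) {
    extra_mat <- matrix(rnorm(n * length(extra)), nrow = n,
                        dimnames = list(NULL, extra))
  }

  patients <- tibble(patient_id, age_group = age_group_levels()[age_idx],
                     gender, payer, income_band, education_band, facility_id)
  if (!is.null(extra_mat)) {
    patients <- bind_cols(patients, as_tibble(extra_mat))
  }

  # --- index discharge dates ----------------------------------------------
  index_date <- calendar_start + sample(365:729, n, replace = TRUE)

  # --- look-back utilization ----------------------------------------------
  lab_mult <- med_mult <- rad_mult <- rep(1, n)
  n_I <- rpois(n, 0.35 + 0.12 * chronic_count)
  n_E <- rpois(n, 0.8 + 0.25 * chronic_count)
  n_O <- rpois(n, 2.5 + 0.4 * chronic_count)
  if (any(is_arch)) {
    na <- sum(is_arch)
    # mild lognormal jitter keeps within-archetype spread small relative to
    # the spacing of the planted utilization / burden levels
    jit <- function() exp(rnorm(na, 0, 0.03))
    a_lvl <- map_dbl(archetype[is_arch], ~ profiles[[.x]]$util_level)
    b_lvl <- map_dbl(archetype[is_arch], ~ profiles[[.x]]$burden_level)
    lab_mult[is_arch] <- map_dbl(archetype[is_arch],
                                 ~ profiles[[.x]]$lab_mult) * jit()
    med_mult[is_arch] <- map_dbl(archetype[is_arch],
                                 ~ profiles[[.x]]$med_mult) * jit()
    rad_mult[is_arch] <- map_dbl(archetype[is_arch],
                                 ~ profiles[[.x]]$rad_mult) * jit()
    # archetype encounter volumes are nearly deterministic around their
    # planted level: a dispersed shared volume factor would dominate the
    # residual within-archetype variance and leave the planted clusters
    # elongated rather than isotropic
    n_I[is_arch] <- 1L + 2L * b_lvl + rpois(na, 0.3)
    n_E[is_arch] <- 1L + 2L * a_lvl + rpois(na, 0.3)
    n_O[is_arch] <- 4L + 4L * a_lvl + rpois(na, 0.3)
  }
  n_P <- rpois(n, 0.3)
  n_R <- rpois(n, 0.25 + 0.1 * chronic_count)
  n_old <- rpois(n, 1.2)   # encounters before the look-back window

  counts <- cbind(I = n_I, E = n_E, O = n_O, P = n_P, R = n_R, old = n_old)
  total_enc <- rowSums(counts)

  enc_patient <- rep(seq_len(n), times = total_enc)
  enc_type <- unlist(lapply(seq_len(n), function(i) {
    c(rep("I", n_I[i]), rep("E", n_E[i]), rep("O", n_O[i]),
      rep("P", n_P[i]), rep("R", n_R[i]),
      sample(encounter_type_levels(), n_old[i], replace = TRUE))
  }), use.names = FALSE)
  in_window <- unlist(lapply(seq_len(n), function(i) {
    c(rep(TRUE, total_enc[i] - n_old[i]), rep(FALSE, n_old[i]))
  }), use.names = FALSE)

  m <- length(enc_patient)
  # discharge day offsets before index: look-back window is (index-365, index]
  offset <- integer(m)
  offset[in_window] <- sample(1:364, sum(in_window), replace = TRUE)
  offset[!in_window] <- sample(366:540, sum(!in_window), replace = TRUE)
  discharge_date <- index_date[enc_patient] - offset
  los <- ifelse(enc_type == "I", 1L + rpois(m, 2), 0L)
  admit_date <- discharge_date - los

  base_labs <- c(E = 3, O = 1, I = 8, P = 2, R = 2)
  base_meds <- c(E = 2, O = 3, I = 5, P = 1, R = 2)
  base_rad <- c(E = 1, O = 0.3, I = 2, P = 0.5, R = 0.5)
  n_labs <- rpois(m, base_labs[enc_type] * lab_mult[enc_patient])
  n_meds <- rpois(m, base_meds[enc_type] * med_mult[enc_patient])
  n_radiology <- rpois(m, base_rad[enc_type] * rad_mult[enc_patient])

  flag_string <- function(i) {
    have <- conditions[cond_mat[i, ]]
    if (!length(have)) return("")
    paste(have[runif(length(have)) < 0.6], collapse = ";")
  }
  chronic_flags <- map_chr(enc_patient, flag_string)
  primary_dx <- sprintf("dx%03d", sample.int(50L, m, replace = TRUE))
  secondary_dx <- sprintf("dx%03d", sample.int(50L, m, replace = TRUE))

  history <- tibble(patient_id = patient_id[enc_patient],
                    encounter_type = enc_type,
                    admit_date, discharge_date, chronic_flags,
                    n_labs = as.integer(n_labs), n_meds = as.integer(n_meds),
                    n_radiology = as.integer(n_radiology),
                    primary_dx, secondary_dx)

  # the index inpatient encounter itself
  index_los <- 1L + rpois(n, 3)
  index_enc <- tibble(patient_id,
                      encounter_type = "I",
                      admit_date = index_date - index_los,
                      discharge_date = index_date,
                      chronic_flags = map_chr(seq_len(n), flag_string),
                      n_labs = as.integer(rpois(n, 8 * lab_mult)),
                      n_meds = as.integer(rpois(n, 5 * med_mult)),
                      n_radiology = as.integer(rpois(n, 2 * rad_mult)),
                      primary_dx = sprintf("dx%03d",
                                           sample.int(50L, n, replace = TRUE)),
                      secondary_dx = sprintf("dx%03d",
                                             sample.int(50L, n, replace = TRUE)))

  encounters <- bind_rows(history, index_enc) |>
    arrange(.data$patient_id, .data$discharge_date, .data$encounter_type) |>
    mutate(encounter_id = sprintf("E%08d", row_number()), .before = 1)

  index_encounter_id <- encounters |>
    semi_join(tibble(patient_id, discharge_date = index_date),
              by = c("patient_id", "discharge_date")) |>
    filter(.data$encounter_type == "I") |>
    group_by(.data$patient_id) |>
    slice_tail(n = 1) |>
    ungroup()
  # map back to patient order
  idx_map <- setNames(index_encounter_id$encounter_id,
                      index_encounter_id$patient_id)

  # --- outcome -------------------------------------------------------------
  eff <- config$effect_log_hr
  getf <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  lp <- qlogis(config$baseline_daily_hazard) +
    getf("chronic_count") * chronic_count +
    getf("prior_inpatient") * n_I +
    getf("age_group") * (age_idx - 1) +
    getf("highrisk") * as.numeric(is_arch)
  if (length(extra)) {
    for (nm in extra) lp <- lp + eff[[nm]] * extra_mat[, nm]
  }
  hazard <- plogis(lp)
  true_time <- rgeom(n, hazard) + 1L

  horizon <- config$horizon_days
  censor_time <- rep(horizon, n)
  if (config$admin_censor_prob > 0) {
    hit <- runif(n) < config$admin_censor_prob
    censor_time[hit] <- sample.int(horizon, sum(hit), replace = TRUE)
  }
  observed_time <- pmin(true_time, censor_time)
  event_observed <- true_time <= censor_time

  index_discharges <- tibble(
    index_id = unname(idx_map[patient_id]),
    patient_id,
    discharge_date = index_date,
    true_time_to_readmission = as.integer(true_time),
    event_within_30d = true_time <= 30L,
    observed_time = as.integer(observed_time),
    event_observed,
    true_daily_hazard = hazard,
    archetype = as.integer(archetype))

  list(patients = patients, encounters = encounters,
       index_discharges = index_discharges)
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `patients.csv`, `encounters.csv` and
#' `index_discharges.csv` (UTF-8, header row, ISO-8601 dates) into `path`;
#' `read_cohort()` reads them back. The round trip is lossless, including
#' column order. `read_cohort()` validates the encounter-date invariant and
#' fails naming the offending row and column.
#'
#' @param cohort A list with `patients`, `encounters`, `index_discharges`.
#' @param path Directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort list.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(c("patients", "encounters", "index_discharges") %in%
                  names(cohort)))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$patients, file.path(path, "patients.csv"))
  readr::write_csv(cohort$encounters, file.path(path, "encounters.csv"))
  readr::write_csv(cohort$index_discharges,
                   file.path(path, "index_discharges.csv"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  patients <- readr::read_csv(file.path(path, "patients.csv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                income_band = readr::col_integer(),
                                education_band = readr::col_integer()))
  encounters <- readr::read_csv(file.path(path, "encounters.csv"),
                                show_col_types = FALSE,
                                col_types = readr::cols(
                                  admit_date = readr::col_date(),
                                  discharge_date = readr::col_date(),
                                  chronic_flags = readr::col_character(),
                                  n_labs = readr::col_integer(),
                                  n_meds = readr::col_integer(),
                                  n_radiology = readr::col_integer()))
  index <- readr::read_csv(file.path(path, "index_discharges.csv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             discharge_date = readr::col_date(),
                             true_time_to_readmission = readr::col_integer(),
                             observed_time = readr::col_integer(),
                             archetype = readr::col_integer()))
  if (nrow(encounters)) {
    encounters$chronic_flags[is.na(encounters$chronic_flags)] <- ""
    bad <- which(encounters$discharge_date < encounters$admit_date)
    if (length(bad)) {
      abort(sprintf(paste0("encounters.csv row %d: `discharge_date` precedes ",
                           "`admit_date`"), bad[1]))
    }
    for (col in c("n_labs", "n_meds", "n_radiology")) {
      bad <- which(encounters[[col]] < 0)
      if (length(bad)) {
        abort(sprintf("encounters.csv row %d: `%s` is negative", bad[1], col))
      }
    }
  }
  list(patients = patients, encounters = encounters, index_discharges = index)
}
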