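test_that("look-back window filtering counts exactly the in-window encounters", {
  idx_date <- as.Date("2013-06-01")
  enc <- dplyr::bind_rows(
    enc_row("E1", 30, "E"), enc_row("E2", 200, "E"),
    enc_row("I1", 100, "I", los = 4),
    enc_row("I2", 400, "I", los = 9),      # outside the 365-day window
    enc_row("IDX1", 0, "I", los = 2))      # the index encounter itself
  cohort <- manual_cohort(enc, idx_date)
  f <- aggregate_features(cohort$encounters, cohort$index_discharges,
                          cohort$patients)
  expect_equal(nrow(f), 1)
  expect_equal(f$count_E, 2)
  expect_equal(f$count_I, 1)
  expect_equal(f$los_total, 4)
  expect_equal(f$age_group_idx, 6)   # "50-65" is the 7th bin, 0-based
})

test_that("accumulated length of stay adds across inpatient stays", {
  enc <- dplyr::bind_rows(
    enc_row("I1", 50, "I", los = 3), enc_row("I2", 150, "I", los = 5),
    enc_row("IDX1", 0, "I", los = 1))
  cohort <- manual_cohort(enc)
  f <- aggregate_features(cohort$encounters, cohort$index_discharges,
                          cohort$patients)
  expect_equal(f$los_total, 8)
  expect_equal(f$count_I, 2)
})

test_that("a patient with no look-back encounters gets zero counts but full demographics", {
  enc <- enc_row("IDX1", 0, "I", los = 2)
  cohort <- manual_cohort(enc)
  f <- aggregate_features(cohort$encounters, cohort$index_discharges,
                          cohort$patients)
  expect_equal(f$count_E + f$count_O + f$count_I + f$count_P + f$count_R, 0)
  expect_equal(f$chronic_count, 0)
  expect_equal(f$labs_total, 0)
  expect_equal(f$is_female, 1)
  expect_equal(f$payer_Medicare, 1)
})

test_that("an index discharge without a matching patient errors", {
  cohort <- manual_cohort(enc_row("IDX1", 0, "I"))
  cohort$index_discharges$patient_id <- "GHOST"
  expect_error(
    aggregate_features(cohort$encounters, cohort$index_discharges,
                       cohort$patients),
    "matching patient")
})

test_that("features never read post-index data", {
  cohort <- generate_cohort(ehr_config(n_patients = 80, seed = 21))
  f0 <- aggregate_features(cohort$encounters, cohort$index_discharges,
                           cohort$patients)
  # inject post-index encounters for every patient and recompute
  idx <- cohort$index_discharges
  fake <- cohort$encounters[seq_len(nrow(idx)), ]
  fake$encounter_id <- sprintf("FAKE%05d", seq_len(nrow(idx)))
  fake$patient_id <- idx$patient_id
  fake$encounter_type <- "E"
  fake$admit_date <- idx$discharge_date + 5
  fake$discharge_date <- idx$discharge_date + 5
  fake$n_labs <- 99L
  f1 <- aggregate_features(dplyr::bind_rows(cohort$encounters, fake),
                           cohort$index_discharges, cohort$patients)
  expect_equal(f1, f0)
})

test_that("variance filter drops constants and ranks by scaled variance", {
  set.seed(31)
  n <- 200
  d <- tibble::tibble(index_id = as.character(1:n))
  # binary features on wildly different raw scales: the min-max-scaled
  # variance is p(1-p) regardless of scale, so the planted ranking is known
  for (j in 1:100) {
    p <- j / 101
    d[[sprintf("f%03d", j)]] <- rbinom(n, 1, p) * (10^(j %% 5))
  }
  d$const <- 7
  cols <- c(sprintf("f%03d", 1:100), "const")
  got <- variance_filter(d, 10, cols = cols)
  expect_false("const" %in% got)
  expect_length(got, 10)
  # independent oracle: min-max scale then rank by variance, ties by name
  sv <- vapply(cols, function(nm) {
    x <- d[[nm]]
    r <- range(x)
    if (r[1] == r[2]) return(NA_real_)
    var((x - r[1]) / (r[2] - r[1]))
  }, numeric(1))
  sv <- sv[!is.na(sv)]
  oracle <- names(sv)[order(-sv, names(sv))][1:10]
  expect_equal(got, oracle)
})

test_that("variance filter trivial cases behave", {
  d <- tibble::tibble(index_id = "1", a = 1, b = 2)
  d <- dplyr::bind_rows(d, tibble::tibble(index_id = "2", a = 3, b = 5))
  expect_setequal(variance_filter(d, 5, cols = c("a", "b")), c("a", "b"))
  expect_error(variance_filter(d, 0, cols = c("a", "b")), "positive")
})

test_that("sub-cohort assignment partitions the cohort by the two flags", {
  d <- tibble::tibble(index_id = as.character(1:4),
                      chronic_count = c(2, 0, 1, 0),
                      count_I = c(1, 0, 0, 3))
  got <- assign_subcohort(d)
  expect_equal(as.character(got$subcohort),
               c("CD+IP", "neither", "CD-only", "IP-only"))
  expect_false(any(is.na(got$subcohort)))
  expect_error(assign_subcohort(dplyr::select(d, -"count_I")), "missing")
})

test_that("two identical facilities split one per subgroup with zero volume gap", {
  idx <- tibble::tibble(
    index_id = sprintf("i%02d", 1:20),
    patient_id = sprintf("p%02d", 1:20),
    discharge_date = rep(as.Date("2013-02-10"), 20),
    event_within_30d = rep(c(TRUE, FALSE), 10))
  pats <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                         facility_id = rep(c("FA", "FB"), each = 10))
  sp <- facility_balanced_split(idx, pats, seed = 1)
  by_fac <- table(sp$facility_id, sp$subgroup)
  expect_equal(length(unique(sp$subgroup[sp$facility_id == "FA"])), 1)
  expect_equal(length(unique(sp$subgroup[sp$facility_id == "FB"])), 1)
  expect_false(sp$subgroup[sp$facility_id == "FA"][1] ==
                 sp$subgroup[sp$facility_id == "FB"][1])
})

test_that("four facilities with volumes 10/10/20/20 balance as {10,20} vs {10,20}", {
  vols <- c(FA = 10, FB = 10, FC = 20, FD = 20)
  rows <- unlist(mapply(function(f, v) rep(f, v), names(vols), vols))
  idx <- tibble::tibble(
    index_id = sprintf("i%03d", seq_along(rows)),
    patient_id = sprintf("p%03d", seq_along(rows)),
    discharge_date = as.Date("2013-03-05"),
    event_within_30d = FALSE)
  pats <- tibble::tibble(patient_id = idx$patient_id, facility_id = rows)
  sp <- facility_balanced_split(idx, pats, seed = 1)
  g <- dplyr::distinct(sp, facility_id, subgroup)
  vols_by_group <- split(vols[g$facility_id], g$subgroup)
  expect_equal(sort(unname(vols_by_group[[1]])), c(10, 20))
  expect_equal(sort(unname(vols_by_group[[2]])), c(10, 20))
  # exhaustive oracle: no assignment beats the achieved max-month volume gap
  achieved <- abs(sum(vols_by_group[[1]]) - sum(vols_by_group[[2]]))
  best <- min(vapply(0:15, function(mask) {
    g1 <- names(vols)[bitwAnd(bitwShiftR(mask, 0:3), 1) == 1]
    if (length(g1) %in% c(0, 4)) return(Inf)
    abs(sum(vols[g1]) - sum(vols[setdiff(names(vols), g1)]))
  }, numeric(1)))
  expect_equal(achieved, best)
})

test_that("a single facility cannot be split", {
  idx <- tibble::tibble(index_id = "i1", patient_id = "p1",
                        discharge_date = as.Date("2013-01-15"),
                        event_within_30d = FALSE)
  pats <- tibble::tibble(patient_id = "p1", facility_id = "FA")
  expect_error(facility_balanced_split(idx, pats), "two facilities")
})

test_that("no facility contributes to both blind-test and train/calibration", {
  cohort <- generate_cohort(ehr_config(n_patients = 400, seed = 17))
  sp <- facility_balanced_split(cohort$index_discharges, cohort$patients,
                                seed = 2)
  cross <- table(sp$facility_id, sp$split)
  blind_fac <- rownames(cross)[cross[, "blind_test"] > 0]
  fit_fac <- rownames(cross)[cross[, "train"] > 0 | cross[, "calibration"] > 0]
  expect_length(intersect(blind_fac, fit_fac), 0)
})
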