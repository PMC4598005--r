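#' Configure a full retrospective + prospective pipeline run
#'
#' One seed governs every stochastic stage through named substreams
#' (generation, facility split, per-sub-cohort bootstrap, permutations,
#' clustering restarts), so a rerun with the same configuration reproduces
#' every artifact byte for byte.
#'
#' @param seed Global run seed.
#' @param generator Arguments forwarded to [ehr_config()] (its seed is
#'   derived from `seed` unless given explicitly).
#' @param n_keep Features retained by the variance filter (fit on training
#'   rows only).
#' @param train_fraction Subgroup-1 patient fraction used for training.
#' @param prospective_start First calendar date of the prospective phase;
#'   index discharges before it form the retrospective cohort.
#' @param ntree,mtry,nodesize_min Forest size per sub-cohort model.
#' @param low,high Risk-tier thresholds.
#' @param k_max,cluster_threshold,n_restarts High-risk clustering controls
#'   (see [select_k()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            generator = list(),
                            n_keep = 50,
                            train_fraction = 0.7,
                            prospective_start = as.Date("2013-07-01"),
                            ntree = 100, mtry = NULL, nodesize_min = 3,
                            low = 30, high = 70,
                            k_max = 10, cluster_threshold = 0.2,
                            n_restarts = 10) {
  if (!"seed" %in% names(generator)) {
    generator$seed <- substream_seed(seed, "generator")
  }
  structure(
    list(seed = as.integer(seed),
         generator = do.call(ehr_config, generator),
         n_keep = n_keep, train_fraction = train_fraction,
         prospective_start = as.Date(prospective_start),
         ntree = ntree, mtry = mtry, nodesize_min = nodesize_min,
         low = low, high = high,
         k_max = k_max, cluster_threshold = cluster_threshold,
         n_restarts = n_restarts),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may hold any [pipeline_config()] argument at the top level and
#' an [ehr_config()] argument block under `generator`; `effect_log_hr` is a
#' named mapping of covariate to log hazard ratio.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()] object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("seed: 9", "ntree: 50", "generator:", "  n_patients: 1000"), f)
#' pipeline_config_from_yaml(f)$generator$n_patients
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$generator$effect_log_hr)) {
    raw$generator$effect_log_hr <- unlist(raw$generator$effect_log_hr)
  }
  if (!is.null(raw$prospective_start)) {
    raw$prospective_start <- as.Date(raw$prospective_start)
  }
  do.call(pipeline_config, raw)
}

# Assemble the modelling frame: aggregated look-back features joined to the
# survival outcome columns of each index discharge.
build_model_frame <- function(cohort) {
  feats <- aggregate_features(cohort$encounters, cohort$index_discharges,
                              cohort$patients)
  feats |>
    inner_join(cohort$index_discharges |>
                 select("index_id", "discharge_date", "observed_time",
                        "event_observed", "event_within_30d", "archetype"),
               by = "index_id")
}

evaluate_phase <- function(scored, data, low, high) {
  joined <- scored |>
    inner_join(select(data, "index_id", "observed_time", "event_observed",
                      "event_within_30d"), by = "index_id")
  list(bins = bin_rates(joined),
       tiers = tier_rates(joined),
       auc = c_statistic(joined),
       curves = km_curve(joined),
       n = nrow(joined))
}

report_as_list <- function(ev) {
  list(n = ev$n,
       auc = ev$auc$auc, n_pos = ev$auc$n_pos, n_neg = ev$auc$n_neg,
       bins = as.list(as_tibble(ev$bins) |> mutate(bin = as.character(.data$bin))),
       tiers = as.list(ev$tiers |> mutate(tier = as.character(.data$tier))),
       curves = as.list(ev$curves |> as_tibble()))
}

stage_artifact <- function(manifest, stage, path, t0) {
  bind_rows(manifest,
            tibble(stage = stage, artifact = path,
                   md5 = unname(tools::md5sum(path)),
                   elapsed_s = round(as.numeric(Sys.time()) - t0, 3)))
}

#' Run the retrospective modelling phase
#'
#' Generates (or reuses) the synthetic cohort, aggregates look-back
#' features, variance-filters them on training rows, assigns the four
#' chronic-disease x inpatient-history sub-cohorts, splits retrospective
#' facilities into two balanced subgroups, fits one survival forest per
#' sub-cohort on subgroup-1 training rows, calibrates each to the 0-100 PPV
#' score on subgroup-1 calibration rows, and blind-tests on subgroup 2.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (`model.json`,
#'   `evaluation_retrospective.json`, `manifest_retrospective.json`).
#' @param cohort Optional pre-generated cohort (defaults to
#'   `generate_cohort(config$generator)`).
#' @return A list of class `retro_run`.
#' @export
run_retrospective <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  cohort <- cohort %||% generate_cohort(config$generator)
  data <- build_model_frame(cohort)
  data <- data |>
    left_join(assign_subcohort(data), by = "index_id")

  retro <- data |> filter(.data$discharge_date < config$prospective_start)
  if (!nrow(retro)) abort("retrospective phase: no index discharges before `prospective_start`.")

  split <- facility_balanced_split(
    cohort$index_discharges |>
      semi_join(retro, by = "index_id"),
    cohort$patients, train_fraction = config$train_fraction,
    seed = substream_seed(config$seed, "facility-split"))
  retro <- retro |> left_join(select(split, "index_id", "split"),
                              by = "index_id")

  train <- retro |> filter(.data$split == "train")
  selected <- variance_filter(train, config$n_keep)

  models <- list()
  maps <- list()
  for (sc in subcohort_levels()) {
    tr <- train |> filter(.data$subcohort == sc)
    cal <- retro |> filter(.data$split == "calibration",
                           .data$subcohort == sc)
    if (nrow(tr) < 2 || sum(tr$event_observed) == 0) {
      warn(sprintf("sub-cohort %s has no usable training events; pooling all training rows", sc))
      tr <- train
    }
    if (!nrow(cal)) cal <- retro |> filter(.data$split == "calibration")
    m <- fit_survival_forest(tr, selected,
                             ntree = config$ntree, mtry = config$mtry,
                             nodesize_min = config$nodesize_min,
                             seed = substream_seed(config$seed,
                                                   paste0("forest-", sc)))
    h_cal <- predict(m, cal)
    mp <- fit_calibration(tibble(H30 = h_cal,
                                 event_within_30d = cal$event_within_30d),
                          subcohort = sc)
    models[[sc]] <- m
    maps[[sc]] <- mp
  }

  blind <- retro |> filter(.data$split == "blind_test")
  blind_scores <- unified_scores(blind, models, maps,
                                 low = config$low, high = config$high)
  blind_eval <- evaluate_phase(blind_scores, blind, config$low, config$high)

  manifest <- tibble(stage = character(), artifact = character(),
                     md5 = character(), elapsed_s = numeric())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    model_path <- file.path(out_dir, "model.json")
    write_model(models, maps, selected, config, model_path)
    manifest <- stage_artifact(manifest, "fit", model_path, t0)
    report_path <- file.path(out_dir, "evaluation_retrospective.json")
    jsonlite::write_json(report_as_list(blind_eval), report_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest <- stage_artifact(manifest, "evaluate", report_path, t0)
    jsonlite::write_json(as.list(manifest),
                         file.path(out_dir, "manifest_retrospective.json"),
                         auto_unbox = FALSE, digits = NA)
  }

  structure(
    list(config = config, cohort = cohort, data = data, split = split,
         selected_features = selected, models = models, maps = maps,
         blind_scores = blind_scores, blind_eval = blind_eval,
         manifest = manifest),
    class = "retro_run")
}

#' Run the prospective validation phase
#'
#' Scores every prospective index discharge with its sub-cohort's fitted
#' model and calibration map, evaluates the tiered performance, and runs the
#' high-risk phenotype clustering (PCA + K-means with the reduction-rate
#' rule) on the High-tier encounters.
#'
#' @param config A [pipeline_config()].
#' @param retro Either a `retro_run` object or a path to a `model.json`
#'   written by [run_retrospective()] (the cohort is then regenerated from
#'   `config`, which is deterministic).
#' @param out_dir Optional artifact directory (`scores.csv`,
#'   `evaluation_prospective.json`, `clusters.csv`,
#'   `cluster_selection.csv`, `cluster_profiles.json`).
#' @return A list of class `prospective_run`.
#' @export
run_prospective <- function(config, retro, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  if (is.character(retro)) {
    if (!file.exists(retro)) abort(sprintf("model file not found: %s", retro))
    bundle <- read_model(retro)
    cohort <- generate_cohort(config$generator)
    data <- build_model_frame(cohort) |>
      (\(d) left_join(d, assign_subcohort(d), by = "index_id"))()
    models <- bundle$models
    maps <- bundle$maps
    selected <- bundle$selected_features
  } else {
    stopifnot(inherits(retro, "retro_run"))
    data <- retro$data
    models <- retro$models
    maps <- retro$maps
    selected <- retro$selected_features
  }

  pros <- data |> filter(.data$discharge_date >= config$prospective_start)
  if (!nrow(pros)) {
    warn("prospective cohort is empty; nothing to score or cluster.")
    return(structure(list(config = config, scores = tibble(),
                          eval = NULL, clustering = NULL,
                          manifest = tibble()),
                     class = "prospective_run"))
  }

  scores <- unified_scores(pros, models, maps,
                           low = config$low, high = config$high)
  ev <- evaluate_phase(scores, pros, config$low, config$high)

  high_rows <- pros[scores$tier == "High", , drop = FALSE]
  clustering <- NULL
  if (nrow(high_rows) >= 3) {
    pca <- pca_project(high_rows, feature_cols = selected)
    sel <- select_k(pca, k_max = min(config$k_max, nrow(high_rows)),
                    threshold = config$cluster_threshold,
                    n_restarts = config$n_restarts,
                    seed = substream_seed(config$seed, "clustering"))
    profiles <- profile_clusters(sel, high_rows)
    clustering <- list(pca = pca, selection = sel, profiles = profiles)
  } else {
    warn("fewer than 3 High-tier encounters; skipping clustering.")
  }

  manifest <- tibble(stage = character(), artifact = character(),
                     md5 = character(), elapsed_s = numeric())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    scores_path <- file.path(out_dir, "scores.csv")
    readr::write_csv(scores, scores_path)
    manifest <- stage_artifact(manifest, "score", scores_path, t0)
    report_path <- file.path(out_dir, "evaluation_prospective.json")
    jsonlite::write_json(report_as_list(ev), report_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest <- stage_artifact(manifest, "evaluate", report_path, t0)
    if (!is.null(clustering)) {
      cl_path <- file.path(out_dir, "clusters.csv")
      readr::write_csv(
        clustering$pca$coords |>
          mutate(cluster_id = clustering$selection$assignment),
        cl_path)
      manifest <- stage_artifact(manifest, "cluster", cl_path, t0)
      tr_path <- file.path(out_dir, "cluster_selection.csv")
      readr::write_csv(clustering$selection$trace, tr_path)
      manifest <- stage_artifact(manifest, "cluster", tr_path, t0)
      pr_path <- file.path(out_dir, "cluster_profiles.json")
      jsonlite::write_json(
        list(summary = as.list(clustering$profiles$summary),
             age_distribution = if (!is.null(clustering$profiles$age_distribution))
               as.list(clustering$profiles$age_distribution |>
                         mutate(age_group = as.character(.data$age_group))),
             chronic_prevalence = as.list(clustering$profiles$chronic_prevalence)),
        pr_path, auto_unbox = TRUE, digits = NA, na = "null")
      manifest <- stage_artifact(manifest, "cluster", pr_path, t0)
    }
    jsonlite::write_json(as.list(manifest),
                         file.path(out_dir, "manifest_prospective.json"),
                         auto_unbox = FALSE, digits = NA)
  }

  structure(list(config = config, scores = scores, eval = ev,
                 clustering = clustering, manifest = manifest),
            class = "prospective_run")
}

#' Run the full pipeline end to end
#'
#' [run_retrospective()] followed by [run_prospective()], writing a combined
#' `scores.csv` (blind-test plus prospective rows, tagged by phase) when
#' `out_dir` is given.
#'
#' @inheritParams run_retrospective
#' @return List with elements `retrospective` and `prospective`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  retro <- run_retrospective(config, out_dir = out_dir)
  pros <- run_prospective(config, retro, out_dir = out_dir)
  if (!is.null(out_dir)) {
    combined <- bind_rows(
      retro$blind_scores |> mutate(phase = "retrospective_blind_test"),
      pros$scores |> mutate(phase = "prospective"))
    readr::write_csv(combined, file.path(out_dir, "scores.csv"))
  }
  list(retrospective = retro, prospective = pros)
}
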