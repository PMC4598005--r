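#' Serialize fitted models and calibration maps to JSON
#'
#' Writes the four sub-cohort forests (trees as nested node/leaf arrays),
#' their calibration maps, the selected feature list and the run
#' configuration into a single JSON document, and reads them back with all
#' classes restored. The document is plain text and byte-deterministic for a
#' given fit.
#'
#' @param models Named list of [fit_survival_forest()] objects.
#' @param maps Named list of [fit_calibration()] objects (same names).
#' @param selected_features Character vector of the features the models use.
#' @param config The run configuration to echo into the document.
#' @param path Output file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a list with `models`, `maps`, `selected_features`, `config`.
#' @export
write_model <- function(models, maps, selected_features, config, path) {
  if (inherits(config, "pipeline_config")) {
    config <- unclass(config)
    config$generator <- unclass(config$generator)
    config$prospective_start <- as.character(config$prospective_start)
  } else if (inherits(config, "ehr_config")) {
    config <- unclass(config)
  }
  doc <- list(
    package = "readmitrsf",
    selected_features = selected_features,
    config = config,
    models = lapply(models, function(m) {
      list(features = m$features, config = m$config, n = m$n,
           n_events = m$n_events, trees = m$trees)
    }),
    maps = lapply(maps, function(mp) {
      list(subcohort = mp$subcohort, n = mp$n, base_rate = mp$base_rate,
           knots = as.list(mp$knots))
    }))
  # I(17) significant digits: doubles survive the decimal round trip exactly,
  # so a model reloaded from JSON predicts bit-identically
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  restore_tree <- function(tr) {
    list(split_col = vapply(tr$split_col, as.integer, integer(1)),
         split_val = vapply(tr$split_val,
                            function(v) if (is.null(v)) NA_real_ else
                              as.numeric(v), numeric(1)),
         left = vapply(tr$left, as.integer, integer(1)),
         right = vapply(tr$right, as.integer, integer(1)),
         leaf_id = vapply(tr$leaf_id, as.integer, integer(1)),
         leaf_times = lapply(tr$leaf_times,
                             function(v) as.numeric(unlist(v))),
         leaf_H = lapply(tr$leaf_H, function(v) as.numeric(unlist(v))))
  }
  models <- lapply(doc$models, function(m) {
    cfg <- m$config
    structure(
      list(trees = lapply(m$trees, restore_tree),
           features = as.character(unlist(m$features)),
           config = list(ntree = as.integer(cfg$ntree),
                         mtry = as.integer(cfg$mtry),
                         nodesize_min = as.integer(cfg$nodesize_min),
                         chf_method = cfg$chf_method,
                         horizon_days = cfg$horizon_days,
                         bootstrap = isTRUE(cfg$bootstrap),
                         seed = as.integer(cfg$seed)),
           n = m$n, n_events = m$n_events),
      class = "readmit_rsf")
  })
  maps <- lapply(doc$maps, function(mp) {
    structure(
      list(knots = tibble(
             h = as.numeric(unlist(mp$knots$h)),
             n_at_or_above = as.integer(unlist(mp$knots$n_at_or_above)),
             ppv_raw = as.numeric(unlist(mp$knots$ppv_raw)),
             ppv = as.numeric(unlist(mp$knots$ppv)),
             score = as.numeric(unlist(mp$knots$score))),
           subcohort = mp$subcohort, n = mp$n, base_rate = mp$base_rate),
      class = "calibration_map")
  })
  list(models = models, maps = maps,
       selected_features = as.character(unlist(doc$selected_features)),
       config = doc$config)
}
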