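#' Log-rank split statistic for a candidate cut
#'
#' Computes the signed standardized log-rank statistic
#' \deqn{F(x,c) = \frac{\sum_i (d_{i,1} - Y_{i,1} d_i / Y_i)}
#'   {\sqrt{\sum_i \frac{Y_{i,1}}{Y_i}\big(1-\frac{Y_{i,1}}{Y_i}\big)
#'    \frac{Y_i - d_i}{Y_i - 1} d_i}}}
#' over the distinct event times of the node, where daughter 1 holds the
#' samples with `feature <= cut`. Terms with a single sample at risk
#' contribute zero to the denominator. `|F|` measures node separation; the
#' split search maximizes it.
#'
#' @param data Data frame with one row per sample.
#' @param feature Name of the predictor column.
#' @param cut Candidate split value.
#' @param time_col,event_col Names of the observed-time and event-indicator
#'   columns.
#' @return The signed statistic, or `NA` when the split is invalid (an empty
#'   daughter, no events, or a degenerate denominator).
#' @export
logrank_statistic <- function(data, feature, cut,
                              time_col = "observed_time",
                              event_col = "event_observed") {
  cpp_logrank(as.numeric(data[[time_col]]),
              as.integer(as.logical(data[[event_col]])),
              as.numeric(data[[feature]]), cut)
}

#' Best log-rank split over candidate features
#'
#' Exhaustively evaluates every midpoint between consecutive distinct
#' observed values of each candidate feature and returns the
#' (feature, cut) pair maximizing `|F|`. Ties are broken by the
#' alphabetically lower feature name, then the lower cut.
#'
#' @inheritParams logrank_statistic
#' @param candidate_features Features to search (e.g. an mtry draw).
#' @return A one-row tibble `feature`, `cut`, `statistic`, or `NULL` when no
#'   valid split exists.
#' @export
best_split <- function(data, candidate_features,
                       time_col = "observed_time",
                       event_col = "event_observed") {
  X <- as.matrix(data[candidate_features])
  res <- cpp_best_split(as.numeric(data[[time_col]]),
                        as.integer(as.logical(data[[event_col]])),
                        X,
                        seq_along(candidate_features),
                        as.integer(rank(candidate_features)))
  if (!res$valid) return(NULL)
  tibble(feature = candidate_features[res$col], cut = res$cut,
         statistic = res$F)
}

#' Terminal-node cumulative hazard estimate
#'
#' Nelson-Aalen estimator \eqn{H(t) = \sum_{t_i \le t} d_i / Y_i} over a
#' node's samples (default), or the `-log` Kaplan-Meier alternative matching
#' the identity \eqn{H = -\log S} (survival floored at 1e-12 so fully
#' eventful nodes stay finite).
#'
#' @inheritParams logrank_statistic
#' @param method `"nelson-aalen"` or `"neg-log-km"`.
#' @return Tibble `time`, `chf`: a right-continuous non-decreasing step
#'   function, 0 before the first event time.
#' @export
terminal_chf <- function(data, time_col = "observed_time",
                         event_col = "event_observed",
                         method = c("nelson-aalen", "neg-log-km")) {
  if (nrow(data) == 0) abort("cannot estimate a hazard from zero samples.")
  method <- match.arg(method)
  res <- cpp_terminal_chf(as.numeric(data[[time_col]]),
                          as.integer(as.logical(data[[event_col]])),
                          if (method == "nelson-aalen") 1L else 2L)
  tibble(time = res$times, chf = res$H)
}

#' Fit a random survival forest
#'
#' Bagged log-rank survival trees: each of `ntree` trees is grown on a
#' with-replacement bootstrap resample of the training rows; at every node a
#' fresh random draw of `mtry` candidate predictors is searched exhaustively
#' for the cut maximizing the absolute log-rank statistic; terminal nodes
#' carry the Nelson-Aalen cumulative hazard of their samples. The ensemble
#' prediction is the plain average of the per-tree terminal hazards,
#' \eqn{H^e(t|x) = \frac{1}{ntree}\sum_b H^b(t|x)}.
#'
#' @param data Data frame holding predictors plus time and event columns.
#' @param features Character vector of predictor column names.
#' @param time_col,event_col Observed time (days from discharge to
#'   readmission or censoring) and event indicator columns.
#' @param ntree Number of trees.
#' @param mtry Candidate predictors per node; default `ceiling(sqrt(p))`.
#' @param nodesize_min Minimum node size to attempt a split. 1 grows trees to
#'   purity; the default 3 trades a little purity for stability.
#' @param chf_method Terminal hazard estimator (see [terminal_chf()]).
#' @param horizon_days Scoring horizon `t*` used by `predict()` by default.
#' @param bootstrap Set `FALSE` to grow every tree on the full sample
#'   (single-tree reduction used by tests).
#' @param seed Seed for the bootstrap and mtry draws.
#' @return An object of class `readmit_rsf`.
#' @export
#' @examples
#' cohort <- generate_cohort(ehr_config(n_patients = 300, seed = 7))
#' feats <- aggregate_features(cohort$encounters, cohort$index_discharges,
#'                             cohort$patients)
#' d <- dplyr::inner_join(feats, cohort$index_discharges, by = "index_id")
#' fit <- fit_survival_forest(d, c("chronic_count", "count_I", "count_E"),
#'                            ntree = 20, seed = 1)
#' head(predict(fit, d))
fit_survival_forest <- function(data, features,
                                time_col = "observed_time",
                                event_col = "event_observed",
                                ntree = 300, mtry = NULL, nodesize_min = 3,
                                chf_method = c("nelson-aalen", "neg-log-km"),
                                horizon_days = 30, bootstrap = TRUE,
                                seed = 1) {
  chf_method <- match.arg(chf_method)
  miss <- setdiff(c(features, time_col, event_col), names(data))
  if (length(miss)) {
    abort(sprintf("columns not found in `data`: %s",
                  paste(miss, collapse = ", ")))
  }
  event <- as.integer(as.logical(data[[event_col]]))
  if (sum(event) == 0) {
    abort("no events in the training data; a survival forest cannot be fit.")
  }
  if (nrow(data) < 1) abort("empty training data.")
  p <- length(features)
  mtry <- mtry %||% ceiling(sqrt(p))
  if (mtry < 1 || mtry > p) abort("`mtry` must be between 1 and length(features).")
  X <- as.matrix(data[features])
  storage.mode(X) <- "double"
  trees <- withr::with_seed(
    substream_seed(seed, "forest"),
    cpp_fit_forest(X, as.numeric(data[[time_col]]), event,
                   as.integer(ntree), as.integer(mtry),
                   as.integer(nodesize_min),
                   if (chf_method == "nelson-aalen") 1L else 2L,
                   bootstrap, as.integer(rank(features))))
  structure(
    list(trees = trees,
         features = features,
         config = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                       nodesize_min = as.integer(nodesize_min),
                       chf_method = chf_method,
                       horizon_days = horizon_days,
                       bootstrap = bootstrap, seed = as.integer(seed)),
         n = nrow(data),
         n_events = sum(event)),
    class = "readmit_rsf")
}

#' Predict the ensemble cumulative hazard
#'
#' Drops each row of `new_data` down every tree and averages the terminal
#' cumulative hazards at time `t`.
#'
#' @param object A fitted [fit_survival_forest()] model.
#' @param new_data Data frame containing the model's feature columns.
#' @param t Evaluation time in days (default the fitted scoring horizon).
#' @param ... Unused.
#' @return Numeric vector of \eqn{H^e(t|x)}, one per row.
#' @export
predict.readmit_rsf <- function(object, new_data,
                                t = object$config$horizon_days, ...) {
  miss <- setdiff(object$features, names(new_data))
  if (length(miss)) {
    abort(sprintf("feature(s) missing from `new_data`: %s",
                  paste(miss, collapse = ", ")))
  }
  X <- as.matrix(new_data[object$features])
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("`new_data` contains missing feature values.")
  cpp_predict_forest(object$trees, X, t)
}

#' @export
print.readmit_rsf <- function(x, ...) {
  cat(sprintf(
    "Random survival forest: %d trees, %d features (mtry %d), %d samples (%d events)\n",
    x$config$ntree, length(x$features), x$config$mtry, x$n, x$n_events))
  invisible(x)
}

#' @describeIn fit_survival_forest `tidy()` returns per-feature split usage
#'   counts across the forest.
#' @param x A `readmit_rsf` object.
#' @param ... Unused.
#' @export
tidy.readmit_rsf <- function(x, ...) {
  used <- unlist(lapply(x$trees, function(tr) tr$split_col))
  used <- used[used >= 0] + 1L
  tibble(feature = x$features,
         n_splits = as.integer(tabulate(used, nbins = length(x$features)))) |>
    arrange(desc(.data$n_splits), .data$feature)
}

#' @describeIn fit_survival_forest `glance()` returns a one-row model
#'   summary.
#' @export
glance.readmit_rsf <- function(x, ...) {
  tibble(ntree = x$config$ntree, mtry = x$config$mtry,
         nodesize_min = x$config$nodesize_min,
         n = x$n, n_events = x$n_events,
         horizon_days = x$config$horizon_days)
}

#' Permutation importance of the forest features
#'
#' For each feature, permutes its column in the evaluation data (under a
#' seeded stream), recomputes the calibrated risk (score / 100) and reports
#' the increase in mean-square error against the binary 30-day readmission
#' label relative to the unpermuted baseline. Features used by no tree have
#' importance exactly 0.
#'
#' @param model A fitted [fit_survival_forest()] model.
#' @param data Evaluation rows with feature columns and the 30-day label.
#' @param label_col Name of the binary 30-day label column.
#' @param map Optional [fit_calibration()] map used to rescale the ensemble
#'   hazard to a score; fitted on `data` itself when omitted.
#' @param seed Seed of the permutation stream.
#' @return Tibble `feature`, `importance`, sorted by decreasing importance.
#' @export
permutation_importance <- function(model, data,
                                   label_col = "event_within_30d",
                                   map = NULL, seed = 1) {
  y <- as.numeric(data[[label_col]])
  h0 <- predict(model, data)
  if (is.null(map)) {
    map <- fit_calibration(tibble(H = h0, label = y), h_col = "H",
                           label_col = "label")
  }
  p0 <- risk_score(map, h0) / 100
  mse0 <- mean((p0 - y)^2)
  perms <- withr::with_seed(
    substream_seed(seed, "permutation"),
    lapply(model$features, function(f) sample.int(nrow(data))))
  imp <- map_dbl(seq_along(model$features), function(j) {
    d <- data
    d[[model$features[j]]] <- d[[model$features[j]]][perms[[j]]]
    pj <- risk_score(map, predict(model, d)) / 100
    mean((pj - y)^2) - mse0
  })
  tibble(feature = model$features, importance = imp) |>
    arrange(desc(.data$importance), .data$feature)
}

#' Iterative forward feature selection
#'
#' Ranks features by permutation importance from a full-feature fit, starts
#' from the top 10, and adds features in descending importance in batches.
#' After each step the forest is refit, calibrated, and evaluated on the
#' calibration set at the high-risk threshold (score >= 70): sensitivity,
#' specificity and PPV are recorded and the Youden-style combined criterion
#' (sensitivity + specificity - 1) drives the stopping rule. Selection stops
#' once the criterion has failed to improve by more than `tol` for
#' `patience` consecutive steps; the best-scoring feature set is returned.
#'
#' @param train,calibration Data frames of training and calibration rows
#'   (features plus survival columns plus the 30-day label).
#' @param features Full candidate feature set.
#' @param label_col Binary 30-day label column.
#' @param batch_size Features added per step.
#' @param tol Minimum improvement that counts as progress.
#' @param patience Number of non-improving steps tolerated before stopping.
#' @param high_threshold Score threshold defining a high-risk call.
#' @param seed Seed (importance permutations and refits).
#' @param ... Passed to [fit_survival_forest()] (e.g. `ntree`,
#'   `nodesize_min`).
#' @inheritParams fit_survival_forest
#' @return List with `selected` (character vector) and `trace` (a tibble of
#'   per-step metrics).
#' @export
forward_feature_selection <- function(train, calibration, features,
                                      time_col = "observed_time",
                                      event_col = "event_observed",
                                      label_col = "event_within_30d",
                                      batch_size = 5, tol = 1e-6,
                                      patience = 2, high_threshold = 70,
                                      seed = 1, ...) {
  if (length(features) <= 10) {
    return(list(selected = features, trace = tibble()))
  }
  full_fit <- fit_survival_forest(train, features, time_col = time_col,
                                  event_col = event_col,
                                  seed = substream_seed(seed, "fs-full"), ...)
  imp <- permutation_importance(full_fit, calibration, label_col = label_col,
                                seed = substream_seed(seed, "fs-imp"))
  ranking <- imp$feature

  eval_set <- function(feats, step) {
    fit <- fit_survival_forest(train, feats, time_col = time_col,
                               event_col = event_col,
                               seed = substream_seed(seed, paste0("fs-", step)),
                               ...)
    h <- predict(fit, calibration)
    m <- fit_calibration(tibble(H = h, label = calibration[[label_col]]),
                         h_col = "H", label_col = "label")
    s <- risk_score(m, h)
    y <- as.logical(calibration[[label_col]])
    call_high <- s >= high_threshold
    sens <- if (sum(y)) sum(call_high & y) / sum(y) else 0
    spec <- if (sum(!y)) sum(!call_high & !y) / sum(!y) else 0
    ppv <- if (sum(call_high)) sum(call_high & y) / sum(call_high) else NA_real_
    tibble(step = step, n_features = length(feats),
           sensitivity = sens, specificity = spec, ppv = ppv,
           criterion = sens + spec - 1)
  }

  current <- ranking[1:10]
  trace <- eval_set(current, 0L)
  best <- list(features = current, criterion = trace$criterion[1])
  stale <- 0L
  step <- 0L
  remaining <- ranking[-(1:10)]
  while (length(remaining) && stale < patience && is.finite(tol)) {
    step <- step + 1L
    add <- head(remaining, batch_size)
    remaining <- setdiff(remaining, add)
    current <- c(current, add)
    row <- eval_set(current, step)
    trace <- bind_rows(trace, row)
    if (row$criterion > best$criterion + tol) {
      best <- list(features = current, criterion = row$criterion)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
  }
  list(selected = best$features, trace = trace)
}
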