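#' Readmission rates in 10 risk bins
#'
#' Buckets scores into the bins \[0,10), \[10,20), ..., \[90,100\] and
#' reports the per-bin 30-day readmission fraction. Empty bins keep `n = 0`
#' and an `NA` rate (a rate is never fabricated from zero patients). The
#' `rate_monotone` column applies the same weighted isotonic regularization
#' as the calibration map (pool-adjacent-violators, weighted by bin size) to
#' the non-empty bins.
#'
#' @param data Data frame of scored samples.
#' @param score_col,label_col Score (0-100) and binary label columns.
#' @return A tibble of class `bin_summary`: `bin`, `bin_lo`, `n`, `n_events`,
#'   `rate`, `rate_monotone`.
#' @export
bin_rates <- function(data, score_col = "score",
                      label_col = "event_within_30d") {
  s <- data[[score_col]]
  y <- as.logical(data[[label_col]])
  lo <- seq(0, 90, by = 10)
  bin_labels <- c(sprintf("[%d,%d)", lo[-10], lo[-10] + 10), "[90,100]")
  idx <- pmin(findInterval(s, lo), 10L)
  out <- tibble(bin = factor(bin_labels, levels = bin_labels),
                bin_lo = lo,
                n = as.integer(tabulate(idx, nbins = 10)),
                n_events = as.integer(tabulate(idx[y], nbins = 10))) |>
    mutate(rate = ifelse(.data$n > 0, .data$n_events / .data$n, NA_real_))
  filled <- !is.na(out$rate)
  mono <- out$rate
  mono[filled] <- pava_increasing(out$rate[filled], out$n[filled])
  out$rate_monotone <- mono
  class(out) <- c("bin_summary", class(out))
  out
}

#' Readmission rates by risk tier
#'
#' @inheritParams bin_rates
#' @param tier_col Tier column (from [assign_tier()]).
#' @return Tibble `tier`, `n`, `n_events`, `rate`.
#' @export
tier_rates <- function(data, tier_col = "tier",
                       label_col = "event_within_30d") {
  data |>
    mutate(.tier = factor(.data[[tier_col]],
                          levels = c("Low", "Intermediate", "High")),
           .y = as.logical(.data[[label_col]])) |>
    group_by(tier = .data$.tier, .drop = FALSE) |>
    summarise(n = n(), n_events = sum(.data$.y), .groups = "drop") |>
    mutate(rate = ifelse(.data$n > 0, .data$n_events / .data$n, NA_real_))
}

#' Kaplan-Meier readmission-free curves per risk tier
#'
#' Product-limit estimate of the probability of remaining readmission-free,
#' evaluated at every integer day 0..`horizon`, stratified by tier.
#' Censoring is respected; events after the horizon count as
#' readmission-free within it.
#'
#' @param data Data frame with observed times, event indicators and tiers.
#' @param time_col,event_col Observed-time and event columns.
#' @param tier_col Stratification column (set `NULL` for a single curve).
#' @param horizon Last day of the curve.
#' @return A tibble of class `readmission_free_curves`: `tier`, `day`,
#'   `survival`.
#' @export
km_curve <- function(data, time_col = "observed_time",
                     event_col = "event_observed", tier_col = "tier",
                     horizon = 30) {
  t30 <- pmin(data[[time_col]], horizon)
  e30 <- as.logical(data[[event_col]]) & data[[time_col]] <= horizon
  grp <- if (is.null(tier_col)) rep("all", nrow(data)) else
    as.character(data[[tier_col]])
  groups <- if (is.null(tier_col)) "all" else
    intersect(c("Low", "Intermediate", "High", sort(unique(grp))), unique(grp))
  out <- list_rbind(map(groups, function(g) {
    sel <- grp == g
    fit <- survival::survfit(
      survival::Surv(t30[sel], e30[sel]) ~ 1)
    sm <- summary(fit, times = 0:horizon, extend = TRUE)
    tibble(tier = g, day = sm$time, survival = sm$surv)
  }))
  class(out) <- c("readmission_free_curves", class(out))
  out
}

#' Binary c-statistic of the risk score
#'
#' Mann-Whitney formulation: the probability that a random readmitted
#' patient's score exceeds a random non-readmitted patient's, counting ties
#' as one half, computed through midranks.
#'
#' @inheritParams bin_rates
#' @return One-row tibble `auc`, `n_pos`, `n_neg`.
#' @export
c_statistic <- function(data, score_col = "score",
                        label_col = "event_within_30d") {
  s <- data[[score_col]]
  y <- as.logical(data[[label_col]])
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("c-statistic requires at least one event and one non-event.")
  }
  r <- rank(s)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tibble(auc = auc, n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))
}

#' Median day of readmission among 30-day events
#'
#' First day at which the conditional distribution of event times among
#' patients readmitted within the horizon reaches 50%, read off a
#' readmission-free curve: the smallest day \eqn{d} with
#' \eqn{1 - S(d) \ge 0.5 (1 - S(horizon))}.
#'
#' @param curves A [km_curve()] result.
#' @return Tibble `tier`, `median_day` (`NA` when a tier has no events).
#' @export
median_time_to_event <- function(curves) {
  horizon <- max(curves$day)
  curves |>
    group_by(.data$tier) |>
    summarise(median_day = {
      s_end <- .data$survival[.data$day == horizon]
      if (s_end >= 1) NA_real_ else
        min(.data$day[1 - .data$survival >= 0.5 * (1 - s_end)])
    }, .groups = "drop")
}

#' @describeIn bin_rates `autoplot()` draws the Fig-2-style bin bar chart.
#' @param object A `bin_summary`.
#' @param ... Unused.
#' @export
autoplot.bin_summary <- function(object, ...) {
  ggplot(filter(object, !is.na(.data$rate)),
         aes(x = .data$bin, y = 100 * .data$rate)) +
    geom_col(fill = "steelblue") +
    labs(x = "risk score bin", y = "30-day readmission rate (%)",
         title = "Readmission rate by risk bin") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @describeIn km_curve `autoplot()` draws the per-tier readmission-free
#'   curves.
#' @param object A `readmission_free_curves` tibble.
#' @param ... Unused.
#' @export
autoplot.readmission_free_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$day, y = .data$survival,
                     colour = .data$tier)) +
    geom_step(direction = "hv", linewidth = 0.8) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "days since index discharge", y = "readmission-free probability",
         colour = "risk tier", title = "Time to readmission by risk tier") +
    theme_minimal()
}
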