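# Weighted isotonic regression (non-decreasing) by pool-adjacent-violators.
# Base R's isoreg() is unweighted; the PPV knots carry very different tail
# sizes, so the pooling must be weighted.
pava_increasing <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  vals <- numeric(n)
  wts <- numeric(n)
  sizes <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    cv <- y[i]
    cw <- w[i]
    cs <- 1L
    while (top > 0L && vals[top] > cv) {
      cv <- (vals[top] * wts[top] + cv * cw) / (wts[top] + cw)
      cw <- wts[top] + cw
      cs <- sizes[top] + cs
      top <- top - 1L
    }
    top <- top + 1L
    vals[top] <- cv
    wts[top] <- cw
    sizes[top] <- cs
  }
  rep(vals[seq_len(top)], sizes[seq_len(top)])
}

#' Fit a PPV-based 0-100 risk calibration map
#'
#' For every observed ensemble hazard value \eqn{h} in the calibration set,
#' the raw positive predictive value is the readmission fraction among the
#' samples with \eqn{H \ge h}. Raw PPV curves are not monotone in finite
#' samples - the subsets above the largest hazards are tiny and their PPVs
#' pure noise - so an isotonic regularization (pool-adjacent-violators,
#' weighted by the size of each tail subset) is applied to enforce a score
#' non-decreasing in \eqn{H} while staying as close as possible to the raw
#' curve. The score is 100 x regularized PPV, so it estimates the
#' percentage of patients at or above that hazard who readmit within 30
#' days.
#'
#' @param data Data frame of calibration samples.
#' @param h_col Column holding the ensemble cumulative hazard
#'   \eqn{H^e(t^*|x)}.
#' @param label_col Binary 30-day readmission label column.
#' @param subcohort Optional sub-cohort tag stored in the map.
#' @return An object of class `calibration_map`.
#' @export
fit_calibration <- function(data, h_col = "H30",
                            label_col = "event_within_30d",
                            subcohort = NA_character_) {
  h <- as.numeric(data[[h_col]])
  y <- as.numeric(as.logical(data[[label_col]]))
  if (!length(h)) abort("calibration set is empty.")
  if (all(y == 1) || all(y == 0)) {
    warn("all calibration labels are identical; the map is degenerate.")
  }
  ord <- order(h)
  h <- h[ord]
  y <- y[ord]
  knots <- unique(h)
  # suffix counts at each distinct h: samples with H >= knot
  n_ge <- length(h) - (match(knots, h) - 1L)
  pos_total <- rev(cumsum(rev(y)))
  pos_ge <- pos_total[match(knots, h)]
  raw <- pos_ge / n_ge
  reg <- pava_increasing(raw, n_ge)
  structure(
    list(knots = tibble(h = knots, n_at_or_above = as.integer(n_ge),
                        ppv_raw = raw, ppv = reg, score = 100 * reg),
         subcohort = subcohort,
         n = length(h), base_rate = mean(y)),
    class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(
    "PPV calibration map (%s): %d knots from %d samples, base rate %.3f\n",
    x$subcohort %||% "unlabelled", nrow(x$knots), x$n, x$base_rate))
  invisible(x)
}

#' @describeIn fit_calibration `tidy()` returns the knot table.
#' @param x A `calibration_map`.
#' @param ... Unused.
#' @export
tidy.calibration_map <- function(x, ...) x$knots

#' @describeIn fit_calibration `glance()` returns a one-row summary.
#' @export
glance.calibration_map <- function(x, ...) {
  tibble(subcohort = x$subcohort, n = x$n, n_knots = nrow(x$knots),
         base_rate = x$base_rate,
         score_min = min(x$knots$score), score_max = max(x$knots$score))
}

#' Map ensemble hazards to the 0-100 risk score
#'
#' Left-step interpolation matching the threshold semantics of PPV: a hazard
#' receives the score of the largest knot not exceeding it; hazards below
#' every knot take the smallest knot's score and hazards above every knot
#' take the largest knot's score (no extrapolation past the observed range).
#'
#' @param map A [fit_calibration()] map.
#' @param h Numeric vector of ensemble hazards.
#' @return Numeric vector of scores in \[0, 100\].
#' @export
risk_score <- function(map, h) {
  stopifnot(inherits(map, "calibration_map"))
  idx <- findInterval(h, map$knots$h)
  idx[idx == 0] <- 1L
  map$knots$score[idx]
}

#' Assign Low / Intermediate / High risk tiers
#'
#' Low is score < `low`, High is score >= `high`, Intermediate is the rest
#' (the conventional 30/70 thresholds by default).
#'
#' @param score Numeric scores in \[0, 100\].
#' @param low,high Tier thresholds.
#' @return Factor with levels `Low`, `Intermediate`, `High`.
#' @export
assign_tier <- function(score, low = 30, high = 70) {
  if (any(!is.na(score) & (score < 0 | score > 100))) {
    abort("scores must lie in [0, 100].")
  }
  factor(ifelse(score < low, "Low",
                ifelse(score >= high, "High", "Intermediate")),
         levels = c("Low", "Intermediate", "High"))
}

#' Score a mixed-sub-cohort table on the unified 0-100 scale
#'
#' Each sample is scored by its own sub-cohort's model and calibration map;
#' because the score is a rank-based PPV, the resulting 0-100 measure is
#' comparable across sub-cohorts even though their raw hazards live on
#' different scales.
#'
#' @param data Feature rows with `index_id` and a `subcohort` column.
#' @param models Named list of [fit_survival_forest()] models, one per
#'   sub-cohort present in `data`.
#' @param maps Named list of [fit_calibration()] maps, same names.
#' @param low,high Tier thresholds passed to [assign_tier()].
#' @return Tibble `index_id`, `subcohort`, `H30`, `score`, `tier`, in the
#'   input row order.
#' @export
unified_scores <- function(data, models, maps, low = 30, high = 70) {
  present <- unique(as.character(data$subcohort))
  missing_m <- setdiff(present, intersect(names(models), names(maps)))
  if (length(missing_m)) {
    abort(sprintf("no fitted model/map for sub-cohort(s): %s",
                  paste(missing_m, collapse = ", ")))
  }
  h <- numeric(nrow(data))
  s <- numeric(nrow(data))
  for (sc in present) {
    rows <- which(as.character(data$subcohort) == sc)
    h[rows] <- predict(models[[sc]], data[rows, , drop = FALSE])
    s[rows] <- risk_score(maps[[sc]], h[rows])
  }
  tibble(index_id = data$index_id,
         subcohort = as.character(data$subcohort),
         H30 = h, score = s, tier = assign_tier(s, low = low, high = high))
}

#' @describeIn fit_calibration `autoplot()` draws the hazard-to-score step
#'   mapping.
#' @param object A `calibration_map`.
#' @export
autoplot.calibration_map <- function(object, ...) {
  ggplot(object$knots, aes(x = .data$h, y = .data$score)) +
    geom_step(direction = "hv") +
    geom_point(aes(y = 100 * .data$ppv_raw), alpha = 0.3, size = 0.7) +
    labs(x = expression(H^e * "(30 | x)"), y = "risk score (0-100)",
         title = "PPV calibration map",
         subtitle = "points: raw PPV; line: regularized score") +
    theme_minimal()
}
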