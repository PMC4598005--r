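test_that("the hand-worked 4-sample log-rank statistic is reproduced", {
  d <- surv_df(c(1, 2, 3, 4), c(1, 1, 1, 1), x = c(0.2, 0.8, 0.3, 0.9))
  # risk-set table by hand: numerator (1-2/4)+(0-1/3)+(1-1/2)+0 = 2/3,
  # denominator 0.25 + 2/9 + 0.25 + 0 = 13/18
  expect_equal(logrank_statistic(d, "x", 0.5), (2 / 3) / sqrt(13 / 18),
               tolerance = 1e-12)
})

test_that("degenerate splits signal invalidity instead of erroring", {
  d <- surv_df(c(1, 2, 3), c(1, 1, 0), x = c(1, 2, 3))
  expect_true(is.na(logrank_statistic(d, "x", 10)))   # daughter 2 empty
  expect_true(is.na(logrank_statistic(d, "x", 0)))    # daughter 1 empty
  # no events at all
  d0 <- surv_df(c(1, 2, 3), c(0, 0, 0), x = c(1, 2, 3))
  expect_true(is.na(logrank_statistic(d0, "x", 1.5)))
})

test_that("squared statistic matches the survdiff log-rank chi-square", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    d <- surv_df(sample(1:25, n, replace = TRUE), rbinom(n, 1, 0.6),
                 x = rnorm(n))
    cut <- stats::median(d$x)
    grp <- d$x <= cut
    if (length(unique(grp)) < 2 || sum(d$event_observed) == 0) next
    F <- logrank_statistic(d, "x", cut)
    if (is.na(F)) next
    sd <- survival::survdiff(
      survival::Surv(d$observed_time, d$event_observed) ~ grp)
    expect_equal(F^2, sd$chisq, tolerance = 1e-8)
  }
})

test_that("best_split reproduces exhaustive enumeration and its tie-breaks", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(8:30, 1)
    d <- surv_df(sample(1:12, n, replace = TRUE), rbinom(n, 1, 0.7),
                 a = rnorm(n), b = sample(0:3, n, replace = TRUE),
                 c = rnorm(n))
    got <- best_split(d, c("a", "b", "c"))
    oracle <- brute_best_split(d, c("a", "b", "c"))
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(abs(got$statistic), oracle$absF, tolerance = 1e-10)
    }
  }
})

test_that("constant candidates give no split; a separating feature is chosen", {
  d <- surv_df(c(1, 2, 8, 9), c(1, 1, 1, 1), flat = rep(2, 4),
               sep = c(0, 0, 1, 1), weak = c(0, 1, 0, 1))
  expect_null(best_split(d, "flat"))
  got <- best_split(d, c("flat", "sep", "weak"))
  expect_equal(got$feature, "sep")
  expect_equal(abs(got$statistic), brute_best_split(d, c("sep", "weak"))$absF,
               tolerance = 1e-12)
})

test_that("terminal Nelson-Aalen hazards match hand computation", {
  one <- terminal_chf(surv_df(5, 1))
  expect_equal(one$time, 5)
  expect_equal(one$chf, 1)  # d/Y = 1/1, and H = 0 before day 5

  three <- terminal_chf(surv_df(c(2, 3, 5), c(1, 0, 1)))
  expect_equal(three$time, c(2, 5))
  expect_equal(three$chf, c(1 / 3, 1 / 3 + 1), tolerance = 1e-12)

  censored <- terminal_chf(surv_df(c(4, 7), c(0, 0)))
  expect_equal(nrow(censored), 0)  # H is identically zero

  expect_error(terminal_chf(surv_df(numeric(0), logical(0))), "zero samples")
})

test_that("the -log Kaplan-Meier alternative agrees with survfit", {
  d <- surv_df(c(2, 3, 5, 5, 8), c(1, 0, 1, 1, 0))
  got <- terminal_chf(d, method = "neg-log-km")
  fit <- survival::survfit(survival::Surv(d$observed_time,
                                          d$event_observed) ~ 1)
  sm <- summary(fit, times = got$time)
  expect_equal(got$chf, -log(sm$surv), tolerance = 1e-12)
})

test_that("a stump forest reduces to the whole-sample Nelson-Aalen curve", {
  set.seed(3)
  d <- surv_df(sample(1:20, 40, replace = TRUE), rbinom(40, 1, 0.5),
               x = rnorm(40))
  fit <- fit_survival_forest(d, "x", ntree = 1, nodesize_min = 100,
                             bootstrap = FALSE, seed = 1)
  na <- terminal_chf(d)
  for (t in c(0, 5, 10, 20)) {
    expect_equal(predict(fit, d[1, ], t = t),
                 c(0, na$chf)[findInterval(t, na$time) + 1],
                 tolerance = 1e-12)
  }
})

test_that("every internal node of a full-mtry tree reproduces the brute-force split", {
  set.seed(19)
  d <- surv_df(sample(1:10, 22, replace = TRUE), rbinom(22, 1, 0.7),
               a = rnorm(22), b = sample(0:2, 22, replace = TRUE),
               c = runif(22))
  fit <- fit_survival_forest(d, c("a", "b", "c"), ntree = 1, mtry = 3,
                             nodesize_min = 3, bootstrap = FALSE, seed = 5)
  check_tree_structure(fit, d, c("a", "b", "c"))
})

test_that("the ensemble hazard is the arithmetic mean of the tree hazards", {
  stump <- function(h30) list(
    split_col = -1L, split_val = NA_real_, left = -1L, right = -1L,
    leaf_id = 0L, leaf_times = list(10), leaf_H = list(h30))
  model <- structure(
    list(trees = list(stump(0.1), stump(0.2), stump(0.6)),
         features = "x",
         config = list(horizon_days = 30), n = 3, n_events = 3),
    class = "readmit_rsf")
  expect_equal(predict(model, tibble::tibble(x = 0)), 0.3, tolerance = 1e-12)
  # single tree: the ensemble equals that tree's leaf hazard
  model$trees <- model$trees[1]
  expect_equal(predict(model, tibble::tibble(x = 0)), 0.1)
})

test_that("fitting is deterministic given the seed and missing features error", {
  set.seed(23)
  d <- surv_df(sample(1:15, 60, replace = TRUE), rbinom(60, 1, 0.5),
               a = rnorm(60), b = rnorm(60))
  f1 <- fit_survival_forest(d, c("a", "b"), ntree = 8, seed = 42)
  f2 <- fit_survival_forest(d, c("a", "b"), ntree = 8, seed = 42)
  expect_identical(predict(f1, d), predict(f2, d))
  expect_error(predict(f1, dplyr::select(d, -"b")), "missing")
  expect_error(fit_survival_forest(dplyr::mutate(d, event_observed = FALSE),
                                   c("a", "b")), "no events")
})

test_that("predicted cumulative hazards are non-negative and non-decreasing in t", {
  set.seed(29)
  d <- surv_df(sample(1:30, 120, replace = TRUE), rbinom(120, 1, 0.5),
               a = rnorm(120), b = rnorm(120))
  fit <- fit_survival_forest(d, c("a", "b"), ntree = 10, seed = 7)
  grid <- 0:30
  for (i in c(1, 7, 50)) {
    H <- vapply(grid, function(t) predict(fit, d[i, ], t = t), numeric(1))
    expect_true(all(H >= 0))
    expect_true(all(diff(H) >= 0))
  }
})

test_that("tree structure is invariant to strictly monotone feature transforms", {
  set.seed(37)
  d <- surv_df(sample(1:12, 50, replace = TRUE), rbinom(50, 1, 0.6),
               a = rnorm(50), b = runif(50))
  # bootstrap off: every row is a training point of every tree, so sample
  # values never fall strictly inside a split gap, where midpoint cuts are
  # not order-equivariant for points the tree never saw
  f1 <- fit_survival_forest(d, c("a", "b"), ntree = 4, mtry = 2, seed = 9,
                            bootstrap = FALSE)
  d2 <- dplyr::mutate(d, a = exp(a), b = b^3)
  f2 <- fit_survival_forest(d2, c("a", "b"), ntree = 4, mtry = 2, seed = 9,
                            bootstrap = FALSE)
  expect_identical(lapply(f1$trees, `[[`, "split_col"),
                   lapply(f2$trees, `[[`, "split_col"))
  expect_identical(lapply(f1$trees, `[[`, "leaf_H"),
                   lapply(f2$trees, `[[`, "leaf_H"))
  expect_identical(predict(f1, d), predict(f2, d2))
})

test_that("ensemble variability across seeds shrinks as the forest grows", {
  set.seed(41)
  d <- surv_df(sample(1:20, 250, replace = TRUE), rbinom(250, 1, 0.4),
               a = rnorm(250), b = rnorm(250), c = rnorm(250))
  probe <- d[1:20, ]
  spread <- function(ntree) {
    preds <- vapply(1:8, function(s)
      predict(fit_survival_forest(d, c("a", "b", "c"), ntree = ntree,
                                  seed = s), probe),
      numeric(nrow(probe)))
    mean(apply(preds, 1, var))
  }
  expect_lt(spread(50), spread(5))
})
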