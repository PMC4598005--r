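#' Two-component PCA projection of high-risk encounters
#'
#' Standardizes each feature and extracts the top two principal components.
#' Utilization counts in encounter data are heavy-tailed with multiplicative
#' noise, so by default non-negative features are `log1p`-transformed
#' (variance stabilization) before z-scoring; features taking negative
#' values - already-centered or signed covariates - are z-scored only.
#' Constant features are dropped with a warning, since they carry no
#' variance to project. Component signs are fixed so the largest-magnitude
#' loading of each component is positive, making the projection
#' deterministic.
#'
#' @param data Feature rows (high-risk encounters), with an optional
#'   `index_id` column carried through.
#' @param feature_cols Features to project (default all numeric feature
#'   columns).
#' @param transform `"log1p"` (default) or `"none"`.
#' @return An object of class `pca_projection` with `coords` (tibble
#'   `index_id`, `pc1`, `pc2`), `loadings`, `explained_variance` and `sdev`.
#' @export
pca_project <- function(data, feature_cols = NULL,
                        transform = c("log1p", "none")) {
  feature_cols <- feature_cols %||% feature_columns(data)
  transform <- match.arg(transform)
  if (nrow(data) < 3) abort("PCA needs at least 3 high-risk encounters.")
  X <- as.matrix(data[feature_cols])
  storage.mode(X) <- "double"
  if (transform == "log1p") {
    nonneg <- apply(X, 2, function(col) min(col) >= 0)
    X[, nonneg] <- log1p(X[, nonneg])
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant feature(s) before PCA",
                 sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) abort("fewer than 2 non-degenerate feature dimensions.")
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = 2)
  if (ncol(pc$rotation) < 2 || pc$sdev[2] == 0) {
    abort("fewer than 2 non-degenerate dimensions after standardization.")
  }
  for (j in 1:2) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  coords <- tibble(
    index_id = if ("index_id" %in% names(data)) data$index_id else
      as.character(seq_len(nrow(data))),
    pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  structure(
    list(coords = coords,
         loadings = tibble(feature = colnames(X),
                           pc1 = pc$rotation[, 1], pc2 = pc$rotation[, 2]),
         explained_variance = pc$sdev[1:2]^2,
         total_variance = sum(apply(Z, 2, var))),
    class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("PCA projection: %d samples, %d features; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$coords), nrow(x$loadings),
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

as_coord_matrix <- function(coords) {
  if (inherits(coords, "pca_projection")) coords <- coords$coords
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[vapply(coords, is.numeric, logical(1))])
  }
  coords
}

#' Seeded K-means with the total within-cluster sum of squares
#'
#' Runs Lloyd's algorithm from `n_restarts` seeded random initializations
#' (plus an optional warm start) and keeps the solution with the lowest
#' total within-cluster sum of squares
#' \eqn{TWSS = \sum_{clusters}\sum_{points} \|x - centroid\|^2}.
#'
#' @param coords A matrix / data frame of coordinates or a
#'   [pca_project()] object.
#' @param k Number of clusters (`k <= n`).
#' @param n_restarts Random restarts.
#' @param seed Seed of the initialization stream.
#' @param init_centers Optional extra initial-center matrix (warm start).
#' @return List `assignment` (integer vector), `centers`, `twss`,
#'   `withinss` (per cluster).
#' @export
kmeans_twss <- function(coords, k, n_restarts = 10, seed = 1,
                        init_centers = NULL) {
  X <- as_coord_matrix(coords)
  n <- nrow(X)
  if (k > n) abort("`k` cannot exceed the number of points.")
  distinct <- unique(X)
  if (nrow(distinct) <= k) {
    # every distinct point its own centroid: TWSS is exactly 0
    assignment <- match(
      apply(X, 1, paste, collapse = "\r"),
      apply(distinct, 1, paste, collapse = "\r"))
    return(list(assignment = assignment, centers = distinct, twss = 0,
                withinss = rep(0, nrow(distinct))))
  }
  if (k == 1) {
    ctr <- colMeans(X)
    return(list(assignment = rep(1L, n), centers = matrix(ctr, nrow = 1),
                twss = sum(sweep(X, 2, ctr)^2),
                withinss = sum(sweep(X, 2, ctr)^2)))
  }
  run <- function(centers) {
    tryCatch(
      kmeans(X, centers = centers, iter.max = 300, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(kmeans(X, centers = centers, iter.max = 300,
                                algorithm = "Lloyd"))
      })
  }
  best <- NULL
  withr::with_seed(substream_seed(seed, "kmeans"), {
    starts <- lapply(seq_len(n_restarts), function(i) {
      distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    })
    if (!is.null(init_centers) && nrow(init_centers) == k) {
      starts <- c(list(init_centers), starts)
    }
    for (st in starts) {
      fit <- run(st)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) abort("k-means failed to converge from any start.")
  list(assignment = as.integer(best$cluster), centers = best$centers,
       twss = best$tot.withinss, withinss = best$withinss)
}

#' Choose the number of clusters by the TWSS reduction rate
#'
#' Computes `TWSS_k` for `k = 1..k_max` (each `k` reuses the previous best
#' solution as a warm start, so the trace is non-increasing) and the
#' reduction rate \eqn{R_k = (TWSS_{k-1} - TWSS_k) / TWSS_{k-1}} for
#' `k >= 2`. The chosen `K` is the largest `k` with `R_k > threshold`; when
#' no `k` qualifies, `K = 1` with a warning. The `k` at which `R_k` peaks is
#' reported alongside, since the two rules can disagree.
#'
#' @inheritParams kmeans_twss
#' @param k_max Largest `k` examined.
#' @param threshold Reduction-rate threshold (conventionally 0.2).
#' @return An object of class `cluster_selection`: `trace` (tibble `k`,
#'   `twss`, `r_k`), `K`, `k_peak`, `assignment` (for the chosen `K`),
#'   `coords`.
#' @export
select_k <- function(coords, k_max = 15, threshold = 0.2, n_restarts = 10,
                     seed = 1) {
  X <- as_coord_matrix(coords)
  n <- nrow(X)
  k_max <- min(k_max, n)
  if (k_max < 2) abort("`k_max` must be at least 2.")
  fits <- vector("list", k_max)
  twss <- numeric(k_max)
  fits[[1]] <- kmeans_twss(X, 1, n_restarts = 1, seed = seed)
  twss[1] <- fits[[1]]$twss
  for (k in 2:k_max) {
    prev <- fits[[k - 1]]
    warm <- NULL
    if (prev$twss > 0 && nrow(prev$centers) == k - 1) {
      d2 <- rowSums((X - prev$centers[prev$assignment, , drop = FALSE])^2)
      warm <- rbind(prev$centers, X[which.max(d2), ])
    }
    fits[[k]] <- kmeans_twss(X, k, n_restarts = n_restarts,
                             seed = substream_seed(seed, paste0("k", k)),
                             init_centers = warm)
    twss[k] <- min(fits[[k]]$twss, twss[k - 1])
  }
  r_k <- c(NA_real_,
           ifelse(twss[-k_max] > 0, (twss[-k_max] - twss[-1]) / twss[-k_max],
                  0))
  qualifying <- which(!is.na(r_k) & r_k > threshold)
  if (length(qualifying)) {
    K <- max(qualifying)
  } else {
    warn("no k exceeded the reduction-rate threshold; falling back to K = 1")
    K <- 1L
  }
  peaks <- which(!is.na(r_k) & r_k == max(r_k, na.rm = TRUE))
  structure(
    list(trace = tibble(k = seq_len(k_max), twss = twss, r_k = r_k),
         K = as.integer(K), k_peak = as.integer(peaks[1]),
         threshold = threshold,
         assignment = fits[[K]]$assignment,
         withinss = fits[[K]]$withinss,
         coords = X),
    class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("Cluster selection: K = %d (largest k with R_k > %.2f); R_k peaks at k = %d\n",
              x$K, x$threshold, x$k_peak))
  invisible(x)
}

#' @describeIn select_k `tidy()` returns the `(k, TWSS_k, R_k)` trace.
#' @param x A `cluster_selection`.
#' @param ... Unused.
#' @export
tidy.cluster_selection <- function(x, ...) x$trace

#' @describeIn select_k `glance()` returns a one-row summary.
#' @export
glance.cluster_selection <- function(x, ...) {
  tibble(K = x$K, k_peak = x$k_peak, threshold = x$threshold,
         twss_1 = x$trace$twss[1], twss_K = x$trace$twss[x$K])
}

#' Clinical profiles of the high-risk clusters
#'
#' Per-cluster summaries mirroring the usual phenotype panels: mean lab /
#' radiology / medication counts and chronic-disease burden, the age-group
#' distribution (percentages summing to 100 within a cluster), per-condition
#' prevalence, and the within-cluster sum of squares in the clustering
#' coordinates. Empty clusters are omitted with a warning.
#'
#' @param selection A [select_k()] result (or an integer assignment vector).
#' @param features Feature rows in the same order as the clustered points.
#' @return List of class `cluster_profiles` with `summary`,
#'   `age_distribution` and `chronic_prevalence` tibbles.
#' @export
profile_clusters <- function(selection, features) {
  assignment <- if (inherits(selection, "cluster_selection"))
    selection$assignment else as.integer(selection)
  if (length(assignment) != nrow(features)) {
    abort("assignment must cover every high-risk encounter.")
  }
  coords <- if (inherits(selection, "cluster_selection")) selection$coords
    else NULL
  ks <- seq_len(max(assignment))
  empty <- setdiff(ks, unique(assignment))
  if (length(empty)) {
    warn(sprintf("omitting empty cluster(s): %s",
                 paste(empty, collapse = ", ")))
    ks <- setdiff(ks, empty)
  }
  df <- features |>
    mutate(.cluster = assignment)
  summarise_cluster <- function(k) {
    rows <- df |> filter(.data$.cluster == k)
    wss <- if (!is.null(coords)) {
      sel <- assignment == k
      sum(sweep(coords[sel, , drop = FALSE], 2,
                colMeans(coords[sel, , drop = FALSE]))^2)
    } else NA_real_
    tibble(cluster = k, n = nrow(rows),
           mean_labs = mean(rows$labs_total %||% NA_real_),
           mean_radiology = mean(rows$radiology_total %||% NA_real_),
           mean_medications = mean(rows$meds_total %||% NA_real_),
           mean_chronic_count = mean(rows$chronic_count %||% NA_real_),
           within_ss = wss)
  }
  summary <- list_rbind(map(ks, summarise_cluster))

  age_distribution <- NULL
  if ("age_group_idx" %in% names(df)) {
    age_distribution <- df |>
      mutate(age_group = factor(age_group_levels()[.data$age_group_idx + 1],
                                levels = age_group_levels())) |>
      count(cluster = .data$.cluster, .data$age_group, .drop = FALSE) |>
      group_by(.data$cluster) |>
      mutate(pct = 100 * .data$n / sum(.data$n)) |>
      ungroup() |>
      filter(.data$cluster %in% ks)
  }
  chronic_cols <- grep("^chronic_c", names(df), value = TRUE)
  chronic_prevalence <- NULL
  if (length(chronic_cols)) {
    chronic_prevalence <- df |>
      group_by(cluster = .data$.cluster) |>
      summarise(across(all_of(chronic_cols), ~ mean(.x > 0)),
                .groups = "drop") |>
      tidyr::pivot_longer(-"cluster", names_to = "condition",
                          values_to = "prevalence") |>
      mutate(condition = sub("^chronic_", "", .data$condition))
  }
  structure(list(summary = summary, age_distribution = age_distribution,
                 chronic_prevalence = chronic_prevalence),
            class = "cluster_profiles")
}

#' @describeIn select_k `autoplot()` draws the TWSS / reduction-rate elbow
#'   trace.
#' @param object A `cluster_selection`.
#' @export
autoplot.cluster_selection <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(c("twss", "r_k"), names_to = "metric") |>
    mutate(metric = factor(.data$metric, levels = c("twss", "r_k"),
                           labels = c("TWSS", "reduction rate R[k]")))
  ggplot(na.omit(tr), aes(x = .data$k, y = .data$value)) +
    geom_line() + geom_point(size = 1) +
    geom_vline(xintercept = object$K, linetype = "dashed",
               colour = "firebrick") +
    facet_wrap(~metric, scales = "free_y", ncol = 1,
               labeller = label_parsed) +
    labs(x = "number of clusters k", y = NULL,
         title = sprintf("Cluster-count selection (K = %d)", object$K)) +
    theme_minimal()
}

#' @describeIn pca_project `autoplot()` draws the 2-D factor scores,
#'   coloured by cluster when a `cluster_selection` is supplied.
#' @param object A `pca_projection`.
#' @param selection Optional [select_k()] result for colouring.
#' @param ... Unused.
#' @export
autoplot.pca_projection <- function(object, selection = NULL, ...) {
  d <- object$coords
  if (!is.null(selection)) d$cluster <- factor(selection$assignment)
  p <- ggplot(d, aes(x = .data$pc1, y = .data$pc2)) +
    labs(x = "PC1", y = "PC2", title = "High-risk encounters, PCA factor scores") +
    theme_minimal()
  if (!is.null(selection)) {
    p + geom_point(aes(colour = .data$cluster), alpha = 0.7, size = 0.9)
  } else {
    p + geom_point(alpha = 0.7, size = 0.9)
  }
}
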