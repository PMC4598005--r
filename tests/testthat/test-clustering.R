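planted_coords <- function(centers, n_per, sd = 1, seed = 1) {
  withr::with_seed(seed, do.call(rbind, lapply(centers, function(mu)
    sweep(matrix(rnorm(2 * n_per, sd = sd), ncol = 2), 2, mu, "+"))))
}

test_that("PCA of 2-D centered data is a distance-preserving rotation", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60), ncol = 2)
  })
  X <- scale(X, scale = FALSE)
  X <- sweep(X, 2, apply(X, 2, sd), "/")  # unit variance: z-scoring is a no-op
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- c("u", "v")
  p <- pca_project(d, feature_cols = c("u", "v"), transform = "none")
  got <- as.matrix(p$coords[, c("pc1", "pc2")])
  expect_equal(as.matrix(dist(got)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pc1 variance equals the top eigenvalue of the standardized covariance", {
  withr::with_seed(9, {
    d <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50),
                        e = rnorm(50))
  })
  p <- pca_project(d, feature_cols = names(d), transform = "none")
  ev <- eigen(cov(scale(as.matrix(d))))$values
  expect_equal(var(p$coords$pc1) * 49 / 49, ev[1], tolerance = 1e-8)
  expect_equal(p$explained_variance[1], ev[1], tolerance = 1e-8)
})

test_that("row duplication leaves PCA loadings unchanged", {
  withr::with_seed(10, {
    d <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  })
  p1 <- pca_project(d, feature_cols = names(d), transform = "none")
  p2 <- pca_project(dplyr::bind_rows(d, d), feature_cols = names(d),
                    transform = "none")
  expect_equal(p1$loadings$pc1, p2$loadings$pc1, tolerance = 1e-8)
  expect_equal(p1$loadings$pc2, p2$loadings$pc2, tolerance = 1e-8)
})

test_that("degenerate PCA inputs error or drop constants", {
  d <- tibble::tibble(a = rnorm(10), b = 1)
  expect_error(suppressWarnings(pca_project(d, feature_cols = c("a", "b"))),
               "non-degenerate")
  expect_error(pca_project(tibble::tibble(a = 1:2, b = 2:3),
                           feature_cols = c("a", "b")), "at least 3")
})

test_that("k-means TWSS hits its analytic anchors at k = 1 and k = n", {
  X <- planted_coords(list(c(0, 0), c(6, 6)), 15, seed = 4)
  one <- kmeans_twss(X, 1)
  expect_equal(one$twss, total_ss(X), tolerance = 1e-8)
  full <- kmeans_twss(X, nrow(X), seed = 2)
  expect_equal(full$twss, 0)
  expect_error(kmeans_twss(X, nrow(X) + 1), "exceed")
})

test_that("k-means at k = 2 matches exhaustive minimization on 6 points", {
  X <- rbind(matrix(c(0, 0, .4, .2, .2, .5), ncol = 2, byrow = TRUE),
             matrix(c(9, 9, 9.3, 8.8, 8.9, 9.4), ncol = 2, byrow = TRUE))
  got <- kmeans_twss(X, 2, seed = 3)
  # brute force over all 2-partitions
  best <- Inf
  for (mask in 1:30) {
    g <- bitwAnd(bitwShiftR(mask, 0:5), 1) == 1
    if (all(g) || !any(g)) next
    w <- sum(sweep(X[g, , drop = FALSE], 2,
                   colMeans(X[g, , drop = FALSE]))^2) +
      sum(sweep(X[!g, , drop = FALSE], 2,
                colMeans(X[!g, , drop = FALSE]))^2)
    best <- min(best, w)
  }
  expect_equal(got$twss, best, tolerance = 1e-8)
  expect_equal(sort(table(got$assignment), decreasing = TRUE),
               sort(table(rep(1:2, each = 3)), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("identical points give zero TWSS everywhere and K = 1", {
  X <- matrix(1, nrow = 12, ncol = 2)
  expect_warning(sel <- select_k(X, k_max = 5, seed = 1), "falling back")
  expect_equal(sel$K, 1L)
  expect_true(all(sel$trace$twss == 0))
  expect_true(all(sel$trace$r_k[-1] == 0))
})

test_that("the TWSS trace is monotone and R_k stays within [0, 1]", {
  X <- planted_coords(list(c(0, 0), c(5, 0), c(0, 5), c(5, 5)), 40,
                      sd = 0.8, seed = 6)
  sel <- select_k(X, k_max = 10, seed = 2)
  expect_true(all(diff(sel$trace$twss) <= 1e-9))
  rk <- sel$trace$r_k[-1]
  expect_true(all(rk >= 0 & rk <= 1))
  expect_equal(sel$trace$twss[1], total_ss(X), tolerance = 1e-8)
  # per-cluster within-SS sums back to TWSS at the chosen K
  expect_equal(sum(sel$withinss), sel$trace$twss[sel$K], tolerance = 1e-8)
})

test_that("three well-separated planted clusters are recovered", {
  hits <- 0
  for (s in 1:10) {
    X <- planted_coords(list(c(0, 0), c(10, 0), c(5, 9)), 60, sd = 1,
                        seed = 400 + s)
    hits <- hits + (select_k(X, k_max = 8, seed = s)$K == 3)
  }
  expect_gte(hits, 9)
})

test_that("cluster profiles reproduce hand-computed group summaries", {
  feats <- tibble::tibble(
    index_id = sprintf("i%d", 1:6),
    labs_total = c(1, 2, 3, 10, 20, 30),
    meds_total = c(0, 1, 2, 5, 5, 5),
    radiology_total = c(1, 1, 1, 2, 2, 2),
    chronic_count = c(0, 1, 2, 6, 6, 6),
    chronic_c01 = c(0, 0, 1, 2, 3, 1),
    age_group_idx = c(4, 4, 4, 7, 7, 7))
  prof <- profile_clusters(c(1L, 1L, 1L, 2L, 2L, 2L), feats)
  expect_equal(prof$summary$mean_labs, c(2, 20))
  expect_equal(prof$summary$mean_chronic_count, c(1, 6))
  expect_equal(prof$summary$n, c(3L, 3L))
  expect_equal(prof$chronic_prevalence$prevalence[
    prof$chronic_prevalence$condition == "c01"], c(1 / 3, 1))
  # age percentages sum to 100 within each cluster
  sums <- tapply(prof$age_distribution$pct, prof$age_distribution$cluster, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 0.1)
})

test_that("a single all-encompassing cluster equals the population summary", {
  feats <- tibble::tibble(index_id = sprintf("i%d", 1:5),
                          labs_total = c(3, 4, 5, 6, 7),
                          meds_total = 1, radiology_total = 0,
                          chronic_count = c(1, 1, 2, 2, 4),
                          age_group_idx = c(1, 2, 3, 4, 5))
  prof <- profile_clusters(rep(1L, 5), feats)
  expect_equal(prof$summary$mean_labs, mean(feats$labs_total))
  expect_equal(prof$summary$mean_chronic_count, mean(feats$chronic_count))
})

test_that("empty clusters are omitted with a warning", {
  feats <- tibble::tibble(index_id = c("a", "b"), labs_total = c(1, 2),
                          meds_total = 0, radiology_total = 0,
                          chronic_count = 0, age_group_idx = 3)
  expect_warning(prof <- profile_clusters(c(1L, 3L), feats), "empty")
  expect_equal(prof$summary$cluster, c(1, 3))
})
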