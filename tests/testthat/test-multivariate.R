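centered <- function(X) sweep(X, 2, colMeans(X))

test_that("PCA matches an independent decomposition and handles rank-1 input", {
  set.seed(42)
  X <- centered(matrix(rnorm(20 * 12), 20, 12))
  pca <- nmr_pca(X, 3)
  orc <- stats::prcomp(X, center = FALSE)
  for (a in 1:3) {
    expect_lt(
      min(
        max(abs(pca$scores[, a] - orc$x[, a])),
        max(abs(pca$scores[, a] + orc$x[, a]))
      ),
      1e-8
    )
  }
  expect_equal(
    pca$explained_variance_fraction[1:3],
    unname(orc$sdev[1:3]^2 / sum(orc$sdev^2)),
    tolerance = 1e-10
  )
  # loadings orthonormal; scores reproduce the projection
  G <- crossprod(pca$loadings)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pca$scores, X %*% pca$loadings, tolerance = 1e-8)

  # one informative column: PC1 explains everything
  X1 <- centered(cbind(rnorm(10), 0, 0))
  p1 <- nmr_pca(X1, 1)
  expect_equal(p1$explained_variance_fraction[1], 1)
  expect_error(nmr_pca(X, 15), "n_components")
})

test_that("PLS-DA first weight equals the normalized X'y closed form", {
  set.seed(7)
  X <- centered(matrix(rnorm(16 * 30), 16, 30))
  groups <- rep(c("terrestrial", "marine"), each = 8)
  y <- as.numeric(groups == "marine")
  m <- plsda(X, groups, 2)
  w_oracle <- crossprod(X, y - mean(y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  cosine <- abs(sum(m$weights[, 1] * w_oracle))
  expect_gt(cosine, 1 - 1e-10)
  # scores of different components are orthogonal
  expect_lt(
    abs(sum(m$scores[, 1] * m$scores[, 2])),
    1e-8 * sqrt(sum(m$scores[, 1]^2) * sum(m$scores[, 2]^2))
  )
  # R2Y never decreases with components
  m4 <- plsda(X, groups, 4)
  expect_true(all(diff(m4$R2Ycum) >= -1e-12))
})

test_that("a perfect predictor column gives R2Y near 1 and Q2 near 1", {
  groups <- rep(c("terrestrial", "marine"), each = 8)
  y <- as.numeric(groups == "marine")
  set.seed(8)
  X <- cbind(y - mean(y), centered(matrix(rnorm(16 * 5, sd = 0.01), 16, 5)))
  m <- plsda(X, groups, 1)
  expect_gt(m$R2Y, 0.999)
  q2 <- q2_cross_val(X + 5, groups, 1, n_folds = 4, seed = 1)
  expect_gt(q2, 0.99)
  expect_lte(q2, 1)
})

test_that("row order equivariance: permuting samples permutes scores only", {
  set.seed(9)
  X <- centered(matrix(rnorm(14 * 9), 14, 9))
  groups <- rep(c("marine", "terrestrial"), 7)
  m1 <- plsda(X, groups, 2)
  perm <- sample(14)
  m2 <- plsda(X[perm, ], groups[perm], 2)
  expect_equal(abs(m2$scores), abs(m1$scores[perm, ]), tolerance = 1e-10,
    ignore_attr = TRUE
  )
  expect_equal(m2$R2Y, m1$R2Y, tolerance = 1e-12)
  expect_equal(abs(m2$weights), abs(m1$weights), tolerance = 1e-10)
})

test_that("Q2 is bounded by R2Y and is near or below zero on null data", {
  nm <- default_normalized()
  groups <- group_labels(nm)
  m <- plsda(pareto_scale(nm), groups, 2)
  q2 <- q2_cross_val(nm, groups, 2, 7, seed = 2)
  expect_lte(q2, m$R2Y)
  # structureless noise with shuffled labels: Q2 has no predictive power
  q2_null <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      Xn <- matrix(stats::rlnorm(24 * 30, sdlog = 0.3), 24, 30)
      gn <- sample(rep(c("marine", "terrestrial"), c(18, 6)))
    })
    q2_cross_val(Xn, gn, 2, 7, seed = s)
  }, numeric(1))
  expect_lt(mean(q2_null), 0.1)
})

test_that("fold counts outside the allowed range are rejected", {
  X <- matrix(rnorm(12 * 4), 12, 4)
  groups <- rep(c("marine", "terrestrial"), each = 6)
  expect_error(q2_cross_val(X, groups, 2, n_folds = 1), "n_folds")
  expect_error(q2_cross_val(X, groups, 2, n_folds = 13), "n_folds")
})

test_that("permutation test separates signal from null and is reproducible", {
  nm <- default_normalized()
  groups <- group_labels(nm)
  p1 <- plsda_permutation(nm, groups, n_permutations = 99, seed = 5)
  p2 <- plsda_permutation(nm, groups, n_permutations = 99, seed = 5)
  expect_identical(p1$permuted_Q2, p2$permuted_Q2)
  expect_lte(p1$empirical_p_Q2, 0.05)
  expect_gt(p1$empirical_p_Q2, 0)
  expect_lte(p1$empirical_p_Q2, 1)
  # observed Q2 exceeds virtually every permuted one here
  expect_gt(p1$observed_Q2, max(p1$permuted_Q2) - 1e-9)
  expect_error(
    plsda_permutation(nm, groups, n_permutations = 0),
    "n_permutations"
  )
})

test_that("loading profile orients signs by group difference and bounds |r|", {
  # terrestrial-elevated column -> positive loading; marine-elevated -> negative
  groups <- rep(c("terrestrial", "marine"), each = 6)
  y <- as.numeric(groups == "marine")
  up_terr <- 1 - y
  up_mar <- y
  set.seed(10)
  X <- centered(cbind(
    up_terr + rnorm(12, sd = 1e-4),
    up_mar + rnorm(12, sd = 1e-4),
    rnorm(12)
  ))
  m <- plsda(X, groups, 1)
  prof <- loading_profile(m, X, groups)
  expect_gt(prof$loading[1], 0)
  expect_lt(prof$loading[2], 0)
  expect_true(all(prof$abs_r >= 0 & prof$abs_r <= 1))
  expect_gt(prof$abs_r[1], 0.999) # column is the class indicator
  # a zero-effect, noise-free column has zero back-scaled loading
  X0 <- cbind(X[, 1], `zero` = rep(0, 12))
  m0 <- plsda(X0, groups, 1)
  prof0 <- loading_profile(m0, X0, groups)
  expect_lt(abs(prof0$loading[2]), 1e-10)
})

test_that("critical correlation selection matches the t-distribution inversion", {
  # independent oracle: invert the Pearson test p-value numerically
  oracle <- stats::uniroot(
    function(r) {
      t <- r * sqrt(22 / (1 - r^2))
      2 * stats::pt(-t, 22) - 0.05
    },
    c(0.01, 0.99), tol = 1e-12
  )$root
  expect_equal(critical_correlation(24, 0.05), oracle, tolerance = 1e-8)
  expect_equal(critical_correlation(24, 0.05), 0.404, tolerance = 5e-3)

  prof <- tibble::tibble(
    bin = 1:5, loading = 1,
    abs_r = c(0.1, 0.39, 0.41, 0.8, 0.45)
  )
  class(prof) <- c("loading_profile", class(prof))
  attr(prof, "n_samples") <- 24
  sel <- select_significant_bins(prof, 24, 0.05)
  expect_setequal(sel$bin, c(3, 4, 5))
  # alpha -> 1 selects everything; zero correlations select nothing
  expect_equal(nrow(select_significant_bins(prof, 24, 1 - 1e-9)), 5)
  prof$abs_r <- rep(0, 5)
  expect_equal(nrow(select_significant_bins(prof, 24, 0.05)), 0)
  expect_error(select_significant_bins(prof, 24, 0), "alpha")
})

test_that("STOCSY recovers peak co-membership and rejects excluded drivers", {
  # two-peak metabolite among independent single-peak ones, low noise
  lib <- separated_library(8, two_peak = 1)
  d <- cohort_design(
    library = lib, planted_log2fc = rep(0, 7),
    concentration_cv = 0.5, noise_sd = 1e-4,
    baseline_amplitude = 0, shift_jitter_sd = 0, water_artifact = FALSE,
    n_points = 8192, seed = 21
  )
  co <- simulate_cohort(d)
  nm <- pqn_normalize(bin_spectra(co$spectra, metadata = co$metadata))
  peaks <- co$truth$peaks[co$truth$peaks$metabolite == "met01", ]
  st <- stocsy(nm, peaks$center[1])
  expect_equal(st$correlation[which.min(abs(st$bin - attr(st, "driver")))], 1)
  sib <- which.min(abs(st$bin - peaks$center[2]))
  expect_gte(st$correlation[sib], 0.95)
  # independent metabolites stay uncorrelated
  other_centers <- co$truth$peaks$center[co$truth$peaks$metabolite != "met01"]
  idx <- vapply(other_centers, function(x) which.min(abs(st$bin - x)), integer(1))
  expect_lt(stats::median(abs(st$correlation[idx])), 0.3)
  expect_error(stocsy(nm, 4.9), "excluded")
  expect_error(stocsy(nm, 12), "kept")
})
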