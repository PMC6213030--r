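#' Principal component analysis of a scaled spectral matrix
#'
#' Thin wrapper over the singular value decomposition of the (already
#' centered) scaled matrix: scores = U D, loadings = V, explained
#' variance fractions = d^2 / sum(d^2). Component signs are fixed so the
#' largest-magnitude loading entry of each component is positive.
#'
#' @param scaled An `nmr_scaled` object or a centered numeric matrix.
#' @param n_components Number of components, at most
#'   min(samples - 1, bins).
#' @return An object of class `nmr_pca` with `scores`, `loadings`,
#'   `explained_variance_fraction`, `bin_centers`, `metadata`.
#' @export
nmr_pca <- function(scaled, n_components = 2) {
  X <- value_matrix(scaled)
  k_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components > k_max) {
    stop(sprintf("`n_components` must be <= %d", k_max), call. = FALSE)
  }
  sv <- svd(X)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = scores, loadings = loadings,
      explained_variance_fraction = sv$d^2 / sum(sv$d^2),
      bin_centers = object_bins(scaled),
      metadata = object_metadata(scaled)
    ),
    class = "nmr_pca"
  )
}

#' @export
print.nmr_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf(
    "<nmr_pca> %d components; explained: %s\n", k,
    paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction[seq_len(k)]),
      collapse = ", "
    )
  ))
  invisible(x)
}

value_matrix <- function(x) {
  if (inherits(x, "nmr_binned")) x$values else as.matrix(x)
}
object_bins <- function(x) if (inherits(x, "nmr_binned")) x$bin_centers else NULL
object_metadata <- function(x) if (inherits(x, "nmr_binned")) x$metadata else NULL

# class indicator: terrestrial -> 0, marine -> 1 (fall back to the
# alphabetically later of two labels as the positive class)
encode_groups <- function(groups) {
  lv <- sort(unique(groups))
  if (length(lv) != 2) {
    stop("exactly two group labels are required", call. = FALSE)
  }
  positive <- if ("marine" %in% lv) "marine" else lv[2]
  y <- as.numeric(groups == positive)
  attr(y, "positive") <- positive
  attr(y, "negative") <- setdiff(lv, positive)
  y
}

resolve_groups <- function(x, groups) {
  if (!is.null(groups)) return(groups)
  if (inherits(x, "nmr_binned")) return(group_labels(x))
  stop("`groups` must be supplied", call. = FALSE)
}

# NIPALS PLS1 core on a centered X and centered y.
fit_pls1 <- function(X, y_centered, n_components, tol = 1e-12, maxit = 500) {
  n <- nrow(X)
  p <- ncol(X)
  Xa <- X
  ya <- y_centered
  ssy0 <- sum(ya^2)
  ssx0 <- sum(Xa^2)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  r2y <- r2x <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- as.numeric(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-300) {
      stop(sprintf("PLS component %d did not converge (degenerate weight)", a),
        call. = FALSE
      )
    }
    w <- w / nw
    converged <- FALSE
    for (it in seq_len(maxit)) {
      # for a single y the weight update is a fixed point after one pass;
      # the loop enforces the convergence contract
      w_new <- as.numeric(crossprod(Xa, ya))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) {
        converged <- TRUE
        w <- w_new
        break
      }
      w <- w_new
    }
    if (!converged) {
      stop(sprintf("PLS component %d did not converge", a), call. = FALSE)
    }
    t_a <- as.numeric(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-300) {
      stop(sprintf("PLS component %d did not converge (null scores)", a),
        call. = FALSE
      )
    }
    p_a <- as.numeric(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    r2y[a] <- 1 - sum(ya^2) / ssy0
    r2x[a] <- 1 - sum(Xa^2) / ssx0
  }
  list(W = W, P = P, T = Tm, q = q, R2Ycum = r2y, R2Xcum = r2x)
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis via NIPALS PLS1 against a
#' centered binary class indicator (terrestrial = 0, marine = 1). X is
#' deflated by t p' per component; R2Y is the fraction of class variance
#' explained, R2X the fraction of spectral variance captured.
#'
#' @param x An `nmr_scaled` object (mean-centered matrix) or a centered
#'   numeric matrix.
#' @param groups Two-level group labels; taken from `x`'s metadata when
#'   omitted.
#' @param n_components Number of latent variables (default 2).
#' @return An object of class `nmr_plsda` with `weights`, `loadings`,
#'   `y_loadings`, `scores`, `coefficients`, `R2X`, `R2Y` (and their
#'   per-component cumulative vectors), `class_encoding`, `groups`.
#' @export
plsda <- function(x, groups = NULL, n_components = 2) {
  groups <- resolve_groups(x, groups)
  X <- value_matrix(x)
  if (length(groups) != nrow(X)) {
    stop("`groups` length must match the number of samples", call. = FALSE)
  }
  y <- encode_groups(groups)
  if (min(table(groups)) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  yc <- y - mean(y)
  fit <- fit_pls1(X, yc, n_components)
  rownames(fit$T) <- rownames(X)
  colnames(fit$T) <- paste0("LV", seq_len(n_components))
  # regression vector in the scaled space
  b <- fit$W %*% solve(crossprod(fit$P, fit$W), fit$q)
  structure(
    list(
      n_components = n_components,
      weights = fit$W, loadings = fit$P, y_loadings = fit$q,
      scores = fit$T,
      coefficients = as.numeric(b),
      y_mean = mean(y),
      R2Xcum = fit$R2Xcum, R2Ycum = fit$R2Ycum,
      R2X = fit$R2Xcum[n_components], R2Y = fit$R2Ycum[n_components],
      class_encoding = c(
        stats::setNames(0, attr(y, "negative")),
        stats::setNames(1, attr(y, "positive"))
      ),
      groups = groups,
      bin_centers = object_bins(x),
      metadata = object_metadata(x)
    ),
    class = "nmr_plsda"
  )
}

#' @export
print.nmr_plsda <- function(x, ...) {
  cat(sprintf(
    "<nmr_plsda> %d components; R2X = %.3f, R2Y = %.3f\n",
    x$n_components, x$R2X, x$R2Y
  ))
  invisible(x)
}

#' Predict class indicator values from a PLS-DA model
#'
#' @param object An `nmr_plsda`.
#' @param newdata Matrix in the same (scaled) space as the training data.
#' @param ... Unused.
#' @return Numeric predictions of the 0/1 class indicator.
#' @export
predict.nmr_plsda <- function(object, newdata, ...) {
  newdata <- value_matrix(newdata)
  as.numeric(newdata %*% object$coefficients) + object$y_mean
}

# stratified fold assignment; round-robin within shuffled groups so every
# group with >= 2 samples appears in >= 2 folds (training always two-class)
stratified_folds <- function(groups, n_folds) {
  folds <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X * X) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# Pareto-scale train/test with training-fold parameters only
scale_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sds <- col_sds(Xtr)
  denom <- ifelse(sds == 0, 1, sqrt(sds))
  list(
    train = sweep(sweep(Xtr, 2, mu, "-"), 2, denom, "/"),
    test = sweep(sweep(Xte, 2, mu, "-"), 2, denom, "/")
  )
}

q2_core <- function(X, y, n_components, folds) {
  press <- 0
  for (f in unique(folds)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2) {
      stop("a training fold contains a single class", call. = FALSE)
    }
    sp <- scale_pair(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    fit <- fit_pls1(sp$train, y[!te] - mean(y[!te]), n_components)
    b <- fit$W %*% solve(crossprod(fit$P, fit$W), fit$q)
    yhat <- as.numeric(sp$test %*% b) + mean(y[!te])
    press <- press + sum((y[te] - yhat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Stratified k-fold cross-validation of the class indicator:
#' Q2 = 1 - PRESS/TSS, pooling squared prediction errors of held-out
#' samples over folds. Centering and Pareto scaling are re-estimated on
#' each training split only, so no information leaks from held-out
#' samples.
#'
#' @param x An `nmr_normalized` / `nmr_binned` object or a numeric matrix
#'   of *unscaled* intensities (scaling happens per fold).
#' @param groups Two-level labels; taken from `x` metadata when omitted.
#' @param n_components Number of latent variables (default 2).
#' @param n_folds Number of folds (default 7; must be >= 2 and <= twice
#'   the smaller group).
#' @param seed Integer seed for the fold assignment.
#' @return Numeric Q2 (<= 1; can be negative for models worse than the
#'   mean).
#' @export
q2_cross_val <- function(x, groups = NULL, n_components = 2, n_folds = 7,
                         seed = 1) {
  groups <- resolve_groups(x, groups)
  X <- value_matrix(x)
  y <- encode_groups(groups)
  n_min <- min(table(groups))
  if (n_folds < 2 || n_folds > 2 * n_min) {
    stop("`n_folds` must be in [2, 2 * smaller group size]", call. = FALSE)
  }
  withr::with_seed(seed, {
    folds <- stratified_folds(groups, n_folds)
    q2 <- q2_core(X, y, n_components, folds)
  })
  q2
}

#' Random permutation test of a PLS-DA model
#'
#' Refits the model under uniformly random permutations of the group
#' labels, recording R2Y (full fit on Pareto-scaled data) and Q2
#' (stratified cross-validation) for each permutation. The empirical
#' p-value on Q2 is (1 + #\{permuted Q2 >= observed Q2\}) / (n + 1).
#'
#' @param x An `nmr_normalized` / `nmr_binned` object or unscaled matrix.
#' @param groups Two-level labels; from `x` metadata when omitted.
#' @param n_components,n_folds As in [q2_cross_val()].
#' @param n_permutations Number of label permutations (default 200).
#' @param seed Integer seed (folds and permutations).
#' @return An object of class `plsda_permutation` with `observed_R2Y`,
#'   `observed_Q2`, `permuted_R2Y`, `permuted_Q2`, `empirical_p_Q2`,
#'   `n_permutations`, `seed`.
#' @export
plsda_permutation <- function(x, groups = NULL, n_components = 2,
                              n_folds = 7, n_permutations = 200, seed = 1) {
  if (n_permutations < 1) {
    stop("`n_permutations` must be >= 1", call. = FALSE)
  }
  groups <- resolve_groups(x, groups)
  X <- value_matrix(x)
  y <- encode_groups(groups)
  # full-data Pareto scaling is label-free: compute once
  mu <- colMeans(X)
  sds <- col_sds(X)
  denom <- ifelse(sds == 0, 1, sqrt(sds))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, denom, "/")
  full_r2y <- function(g) {
    yg <- encode_groups(g)
    fit <- fit_pls1(Xs, yg - mean(yg), n_components)
    fit$R2Ycum[n_components]
  }
  withr::with_seed(seed, {
    folds <- stratified_folds(groups, n_folds)
    observed_Q2 <- q2_core(X, y, n_components, folds)
    observed_R2Y <- full_r2y(groups)
    permuted_R2Y <- permuted_Q2 <- numeric(n_permutations)
    for (k in seq_len(n_permutations)) {
      gp <- sample(groups)
      permuted_R2Y[k] <- full_r2y(gp)
      fp <- stratified_folds(gp, n_folds)
      permuted_Q2[k] <- q2_core(X, encode_groups(gp), n_components, fp)
    }
  })
  structure(
    list(
      n_permutations = n_permutations,
      observed_R2Y = observed_R2Y, observed_Q2 = observed_Q2,
      permuted_R2Y = permuted_R2Y, permuted_Q2 = permuted_Q2,
      empirical_p_Q2 =
        (1 + sum(permuted_Q2 >= observed_Q2)) / (n_permutations + 1),
      seed = seed
    ),
    class = "plsda_permutation"
  )
}

#' @export
print.plsda_permutation <- function(x, ...) {
  cat(sprintf(
    "<plsda_permutation> n = %d: observed R2Y = %.3f, Q2 = %.3f, p(Q2) = %.4f\n",
    x$n_permutations, x$observed_R2Y, x$observed_Q2, x$empirical_p_Q2
  ))
  invisible(x)
}

#' Correlation-colored loading profile of a PLS-DA model
#'
#' For every bin, computes a covariance-style back-scaled loading (the
#' covariance of the bin with the first latent-variable scores) and the
#' absolute Pearson correlation of the bin with the class indicator. The
#' loading sign is oriented so that positive means a relatively higher
#' level in the terrestrial group.
#'
#' @param model An `nmr_plsda` fitted on `x`.
#' @param x The `nmr_scaled` object (or matrix) the model was fitted on.
#' @param groups Labels; from `x` metadata or the model when omitted.
#' @return A tibble of class `loading_profile` with columns `bin` (ppm,
#'   when available), `loading`, `abs_r`; attribute `n_samples`.
#' @export
loading_profile <- function(model, x, groups = NULL) {
  X <- value_matrix(x)
  if (ncol(X) != nrow(model$weights)) {
    stop("matrix and model dimensions do not match", call. = FALSE)
  }
  if (is.null(groups)) groups <- model$groups
  y <- encode_groups(groups)
  t1 <- model$scores[, 1]
  covs <- as.numeric(stats::cov(X, t1))
  # orient: t1 correlates with y through q; positive display = higher in
  # the terrestrial (y = 0) group
  s <- sign(stats::cov(t1, y))
  if (s == 0) s <- 1
  loading <- -s * covs
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r[is.na(r)] <- 0
  bins <- object_bins(x)
  out <- tibble::tibble(
    bin = if (is.null(bins)) seq_len(ncol(X)) else bins,
    loading = loading,
    abs_r = abs(r)
  )
  class(out) <- c("loading_profile", class(out))
  attr(out, "n_samples") <- nrow(X)
  out
}

#' Critical Pearson correlation at a given significance level
#'
#' Inverts the exact relation r = t / sqrt(t^2 + df) at the two-sided
#' critical t with df = n - 2.
#'
#' @param n_samples Number of samples (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical |r|.
#' @export
critical_correlation <- function(n_samples, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (n_samples < 4) stop("`n_samples` must be >= 4", call. = FALSE)
  df <- n_samples - 2
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

#' Select bins significantly correlated with class membership
#'
#' Keeps bins whose |r| with the class indicator reaches the two-sided
#' critical Pearson correlation at `alpha` with df = n - 2.
#'
#' @param profile A [loading_profile()].
#' @param n_samples Number of samples (default: taken from the profile).
#' @param alpha Significance level (default 0.05).
#' @return The selected rows of `profile`, with attribute `r_crit`.
#' @export
select_significant_bins <- function(profile, n_samples = NULL, alpha = 0.05) {
  if (is.null(n_samples)) n_samples <- attr(profile, "n_samples")
  r_crit <- critical_correlation(n_samples, alpha)
  out <- profile[profile$abs_r >= r_crit, , drop = FALSE]
  attr(out, "r_crit") <- r_crit
  out
}

#' Metabolites whose annotated bins are PLS-DA-significant
#'
#' Aggregates the bin-level profile to metabolites using the maximum-|r|
#' bin among each metabolite's annotated integration windows; a
#' metabolite is significant when that bin reaches the critical |r|.
#'
#' @param profile A [loading_profile()].
#' @param annotation An annotation tibble (`metabolite`, `ppm_low`,
#'   `ppm_high`).
#' @param n_samples,alpha As in [select_significant_bins()].
#' @return Tibble with `metabolite`, `max_abs_r`, `loading` (at that
#'   bin), `significant`; attribute `r_crit`.
#' @export
significant_metabolites <- function(profile, annotation, n_samples = NULL,
                                    alpha = 0.05) {
  if (is.null(n_samples)) n_samples <- attr(profile, "n_samples")
  r_crit <- critical_correlation(n_samples, alpha)
  out <- annotation |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(win, key) {
      hit <- purrr::map2(win$ppm_low, win$ppm_high, function(lo, hi) {
        which(profile$bin >= lo & profile$bin <= hi)
      })
      idx <- unique(unlist(hit))
      if (length(idx) == 0) {
        return(tibble::tibble(max_abs_r = NA_real_, loading = NA_real_))
      }
      best <- idx[which.max(profile$abs_r[idx])]
      tibble::tibble(
        max_abs_r = profile$abs_r[best],
        loading = profile$loading[best]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = !is.na(.data$max_abs_r) & .data$max_abs_r >= r_crit
    )
  attr(out, "r_crit") <- r_crit
  out
}

#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates the driver bin against every bin across samples. Peaks of
#' the same molecule co-vary through their shared concentration, so high
#' |r| flags candidate sibling resonances of the driver peak.
#'
#' @param x An `nmr_binned` or `nmr_normalized` object.
#' @param driver Driver position in ppm; resolved to the nearest kept bin
#'   center. Positions inside an excluded region are an error.
#' @return A tibble of class `stocsy_result` with columns `bin`,
#'   `correlation`, `covariance`; attribute `driver` (the resolved bin
#'   center).
#' @export
stocsy <- function(x, driver) {
  stopifnot(inherits(x, "nmr_binned"))
  for (reg in x$excluded_regions) {
    if (driver > reg[1] && driver < reg[2]) {
      stop(sprintf(
        "driver %.3f ppm lies in the excluded region (%.2f, %.2f)",
        driver, reg[1], reg[2]
      ), call. = FALSE)
    }
  }
  if (driver < x$kept_range[1] || driver > x$kept_range[2]) {
    stop("driver outside the kept spectral range", call. = FALSE)
  }
  j <- which.min(abs(x$bin_centers - driver))
  d <- x$values[, j]
  r <- suppressWarnings(as.numeric(stats::cor(x$values, d)))
  r[is.na(r)] <- 0
  r[j] <- 1
  covs <- as.numeric(stats::cov(x$values, d))
  out <- tibble::tibble(
    bin = x$bin_centers, correlation = r, covariance = covs
  )
  class(out) <- c("stocsy_result", class(out))
  attr(out, "driver") <- x$bin_centers[j]
  out
}
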