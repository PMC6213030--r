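#' Reference a spectrum to the TSP resonance at 0.00 ppm
#'
#' Shifts the ppm axis so that the maximum intensity inside
#' `search_window` sits exactly at 0.00 ppm (the methyl singlet of TSP,
#' the usual internal chemical-shift standard).
#'
#' @param spectrum An [nmr_spectrum()] whose axis covers `search_window`.
#' @param search_window Two-element ppm interval containing 0.00.
#' @return The spectrum with a shifted axis. If the window contains no
#'   unique maximum (flat signal), a warning is issued and the spectrum is
#'   returned unchanged.
#' @export
reference_to_tsp <- function(spectrum, search_window = c(-0.2, 0.2)) {
  if (search_window[1] > 0 || search_window[2] < 0) {
    stop("`search_window` must contain 0.00 ppm", call. = FALSE)
  }
  if (min(spectrum$ppm) > search_window[1] ||
      max(spectrum$ppm) < search_window[2]) {
    stop("spectrum does not cover the TSP search window", call. = FALSE)
  }
  in_win <- spectrum$ppm >= search_window[1] & spectrum$ppm <= search_window[2]
  y <- spectrum$intensity[in_win]
  if (max(y) == min(y)) {
    warning("flat signal in TSP window; spectrum left unreferenced")
    return(spectrum)
  }
  peak_ppm <- spectrum$ppm[in_win][which.max(y)]
  nmr_spectrum(spectrum$ppm - peak_ppm, spectrum$intensity, sample_id(spectrum))
}

#' Align spectra by global cross-correlation against the median spectrum
#'
#' Each spectrum (interpolated onto the first spectrum's axis when axes
#' differ) is shifted by the integer-point lag that maximizes its
#' cross-correlation with the point-wise median spectrum, bounded by
#' `max_shift` ppm. This is a single global shift per spectrum; no
#' segment-wise alignment is attempted.
#'
#' @param spectra List of >= 2 [nmr_spectrum()] objects with overlapping
#'   axes.
#' @param max_shift Maximum allowed |shift| in ppm (default 0.03).
#' @return The aligned list, with a `shifts` attribute (named numeric,
#'   applied shift in ppm per spectrum).
#' @export
align_spectra <- function(spectra, max_shift = 0.03) {
  if (length(spectra) < 2) stop("need at least 2 spectra", call. = FALSE)
  axis <- spectra[[1]]$ppm
  lo <- max(vapply(spectra, function(s) min(s$ppm), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$ppm), numeric(1)))
  if (lo >= hi) stop("spectra axes do not overlap", call. = FALSE)
  ints <- lapply(spectra, function(s) {
    if (isTRUE(all.equal(s$ppm, axis))) {
      s$intensity
    } else {
      stats::approx(s$ppm, s$intensity, xout = axis, rule = 2)$y
    }
  })
  step <- stats::median(diff(axis))
  max_lag <- max(0L, as.integer(floor(max_shift / step)))
  ref <- apply(do.call(rbind, ints), 2, stats::median)
  shifts <- numeric(length(spectra))
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    lag <- best_lag(ints[[i]], ref, max_lag)
    shifts[i] <- -lag * step
    out[[i]] <- nmr_spectrum(
      axis, shift_by_lag(ints[[i]], lag), sample_id(spectra[[i]])
    )
  }
  names(out) <- vapply(spectra, sample_id, character(1))
  names(shifts) <- names(out)
  attr(out, "shifts") <- shifts
  out
}

# lag maximizing sum(x[t+lag] * ref[t]); positive lag means x sits to the
# right of ref and must be pulled left
best_lag <- function(x, ref, max_lag) {
  if (max_lag == 0L) return(0L)
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(l) {
    n <- length(x)
    if (l >= 0) sum(x[(1 + l):n] * ref[1:(n - l)]) else
      sum(x[1:(n + l)] * ref[(1 - l):n])
  }, numeric(1))
  lags[which.max(score)]
}

shift_by_lag <- function(x, lag) {
  n <- length(x)
  if (lag == 0L) return(x)
  if (lag > 0) c(x[(1 + lag):n], rep(x[n], lag)) else
    c(rep(x[1], -lag), x[1:(n + lag)])
}

#' Baseline correction by asymmetric least squares
#'
#' Estimates a smooth baseline under the spectrum with the asymmetric
#' least squares (ALS) scheme: a second-difference smoothness penalty
#' plus asymmetric weights that let the curve hug points below it while
#' largely ignoring peaks above. The estimate runs on a mean-decimated
#' copy of the spectrum (baselines are slow features) and is
#' interpolated back, which keeps the cost linear and small.
#'
#' @param spectrum An [nmr_spectrum()], or a list of them (corrected
#'   element-wise).
#' @param lambda Smoothness penalty on the decimated grid (default 1e5).
#' @param p Asymmetry weight for points above the baseline
#'   (default 0.001).
#' @param decimate Decimation factor (default 8).
#' @param maxit Maximum reweighting iterations (default 8).
#' @return The baseline-subtracted spectrum (or list of spectra).
#' @export
baseline_correct <- function(spectrum, lambda = 1e5, p = 0.001,
                             decimate = 8, maxit = 8) {
  if (!inherits(spectrum, "nmr_spectrum") && is.list(spectrum)) {
    out <- lapply(spectrum, baseline_correct,
      lambda = lambda, p = p, decimate = decimate, maxit = maxit
    )
    names(out) <- names(spectrum)
    return(out)
  }
  y <- spectrum$intensity
  n <- length(y)
  m <- floor(n / decimate)
  if (m < 10) stop("spectrum too short for baseline estimation", call. = FALSE)
  yd <- colMeans(matrix(y[seq_len(m * decimate)], nrow = decimate))
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- yd
  for (it in seq_len(maxit)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(m, w) + DtD, w * yd))
    w_new <- ifelse(yd > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  baseline <- stats::approx(
    seq(decimate / 2 + 0.5, by = decimate, length.out = m), z,
    xout = seq_len(n), rule = 2
  )$y
  nmr_spectrum(spectrum$ppm, y - baseline, sample_id(spectrum))
}

#' Bin spectra into uniform ppm buckets
#'
#' Segments each spectrum into contiguous bins of width `bin_width` over
#' `kept_range` and integrates (sums) the intensities falling in each bin.
#' Bins are half-open `[low, high)`, so every axis point belongs to exactly
#' one bin; a point exactly at the upper edge of `kept_range` belongs to
#' none. Bins whose center falls strictly inside any excluded region
#' (e.g. the residual-water window) are dropped. At the defaults this
#' yields 590 bins over 0.65-9.50 ppm, 563 after water exclusion.
#'
#' @param spectra List of [nmr_spectrum()] objects covering `kept_range`,
#'   or a single spectrum.
#' @param bin_width Bin width in ppm (default 0.015).
#' @param kept_range Two-element ppm interval (default c(0.65, 9.50)).
#' @param excluded_regions List of ppm intervals to drop (default the
#'   residual-water window c(4.70, 5.10)); use `list()` for none.
#' @param metadata Optional tibble with a `sample_id` column (and
#'   typically `group`), carried along for downstream stages.
#' @return An object of class `nmr_binned`: list with `values`
#'   (samples x bins matrix), `bin_centers`, `bin_width`, `kept_range`,
#'   `excluded_regions`, `sample_ids`, `metadata`.
#' @export
bin_spectra <- function(spectra, bin_width = 0.015,
                        kept_range = c(0.65, 9.50),
                        excluded_regions = list(c(4.70, 5.10)),
                        metadata = NULL) {
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (kept_range[1] >= kept_range[2]) {
    stop("`kept_range` must be an increasing interval", call. = FALSE)
  }
  span <- kept_range[2] - kept_range[1]
  n_full <- floor(span / bin_width + 1e-9)
  remainder <- span - n_full * bin_width
  truncated <- remainder > 1e-6 * bin_width
  n_bins <- n_full + as.integer(truncated)
  edges <- kept_range[1] + bin_width * 0:n_full
  if (truncated) edges <- c(edges, kept_range[2])
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  rows <- lapply(spectra, function(s) {
    if (min(s$ppm) > kept_range[1] + bin_width ||
        max(s$ppm) < kept_range[2] - bin_width) {
      stop(sprintf(
        "spectrum '%s' does not cover the kept range", sample_id(s)
      ), call. = FALSE)
    }
    idx <- floor((s$ppm - kept_range[1]) / bin_width)
    keep <- s$ppm >= kept_range[1] & s$ppm < kept_range[2] &
      idx >= 0 & idx < n_bins
    idx <- pmin(idx[keep], n_bins - 1L) # truncated last bin collects its points
    vals <- numeric(n_bins)
    sums <- rowsum(s$intensity[keep], idx)
    vals[as.integer(rownames(sums)) + 1L] <- sums[, 1]
    vals
  })
  values <- do.call(rbind, rows)
  ids <- vapply(spectra, sample_id, character(1))
  rownames(values) <- ids

  drop <- rep(FALSE, n_bins)
  for (reg in excluded_regions) {
    drop <- drop | (centers > reg[1] & centers < reg[2])
  }
  values <- values[, !drop, drop = FALSE]
  centers <- centers[!drop]
  colnames(values) <- format_ppm(centers)

  if (!is.null(metadata)) {
    metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  }
  structure(
    list(
      values = values, bin_centers = centers, bin_width = bin_width,
      kept_range = kept_range, excluded_regions = excluded_regions,
      sample_ids = ids, metadata = metadata
    ),
    class = "nmr_binned"
  )
}

#' @export
print.nmr_binned <- function(x, ...) {
  cat(sprintf(
    "<%s> %d samples x %d bins (width %.3f ppm, %.2f-%.2f ppm)\n",
    class(x)[1], nrow(x$values), ncol(x$values), x$bin_width,
    x$kept_range[1], x$kept_range[2]
  ))
  invisible(x)
}

#' @method as_tibble nmr_binned
#' @export
as_tibble.nmr_binned <- function(x, ...) {
  out <- tibble::as_tibble(x$values)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), out)
  if (!is.null(x$metadata) && "group" %in% names(x$metadata)) {
    out <- dplyr::bind_cols(
      out[1], tibble::tibble(group = x$metadata$group), out[-1]
    )
  }
  out
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution following the standard quotient
#' procedure: (1) each row is scaled to a total integral of 100;
#' (2) the reference is the per-bin median over rows (unless supplied);
#' (3) each row's quotient is the median of row/reference over bins with
#' positive reference; (4) the row is divided by its quotient. The total
#' per-sample scale factor (area step times quotient) is stored as
#' `dilution_factors`; it is proportional to the physical dilution when
#' the samples share a composition profile.
#'
#' Bins whose reference intensity sits in the noise floor carry no
#' dilution information and corrupt the median quotient; by default the
#' quotient is therefore computed over the signal-carrying half of the
#' bins (reference at or above its positive median). Set
#' `ref_quantile = 0` to use every positive-reference bin.
#'
#' @param binned An `nmr_binned` (all row sums must be positive).
#' @param reference Optional per-bin reference vector.
#' @param ref_quantile Quantile of the positive reference intensities
#'   below which bins are excluded from the quotient (default 0.5).
#' @return An object of class `nmr_normalized` (extends `nmr_binned`) with
#'   `quotients`, `dilution_factors` and `reference` fields.
#' @export
pqn_normalize <- function(binned, reference = NULL, ref_quantile = 0.5) {
  stopifnot(inherits(binned, "nmr_binned"))
  X <- binned$values
  areas <- rowSums(X)
  if (any(areas <= 0)) {
    bad <- binned$sample_ids[areas <= 0]
    stop(sprintf(
      "sample(s) with non-positive total area: %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  Xa <- sweep(X, 1, areas / 100, "/")
  if (is.null(reference)) {
    reference <- apply(Xa, 2, stats::median)
  }
  pos <- reference > 0
  if (!any(pos)) stop("reference spectrum has no positive bins", call. = FALSE)
  if (ref_quantile > 0) {
    pos <- reference >= stats::quantile(reference[pos], ref_quantile)
  }
  quotients <- apply(Xa[, pos, drop = FALSE], 1, function(r) {
    stats::median(r / reference[pos])
  })
  if (any(quotients <= 0)) {
    stop("non-positive quotient encountered", call. = FALSE)
  }
  out <- binned
  out$values <- sweep(Xa, 1, quotients, "/")
  out$quotients <- stats::setNames(quotients, binned$sample_ids)
  out$dilution_factors <- stats::setNames(
    areas / 100 * quotients, binned$sample_ids
  )
  out$reference <- reference
  class(out) <- c("nmr_normalized", "nmr_binned")
  out
}

#' Mean-center and Pareto-scale a normalized matrix
#'
#' Each column x is transformed to (x - mean(x)) / sqrt(sd(x)), with the
#' sample standard deviation (n - 1 denominator). Pareto scaling keeps
#' large peaks influential while up-weighting small ones less aggressively
#' than unit-variance scaling. Zero-variance columns are mean-centered
#' only and flagged.
#'
#' @param normalized An `nmr_normalized` (or `nmr_binned`) with >= 2
#'   samples.
#' @return An object of class `nmr_scaled` with `column_means`,
#'   `column_sds` and logical `zero_variance` fields for
#'   back-transformation.
#' @export
pareto_scale <- function(normalized) {
  stopifnot(inherits(normalized, "nmr_binned"))
  X <- normalized$values
  if (nrow(X) < 2) stop("Pareto scaling needs >= 2 samples", call. = FALSE)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zv <- sds == 0
  denom <- ifelse(zv, 1, sqrt(sds))
  out <- normalized
  out$values <- sweep(sweep(X, 2, mu, "-"), 2, denom, "/")
  out$column_means <- mu
  out$column_sds <- sds
  out$zero_variance <- zv
  class(out) <- c("nmr_scaled", class(normalized))
  out
}

#' Invert Pareto scaling
#'
#' @param scaled An `nmr_scaled`.
#' @return The matrix of pre-scaling values.
#' @export
pareto_unscale <- function(scaled) {
  stopifnot(inherits(scaled, "nmr_scaled"))
  denom <- ifelse(scaled$zero_variance, 1, sqrt(scaled$column_sds))
  sweep(sweep(scaled$values, 2, denom, "*"), 2, scaled$column_means, "+")
}

#' Write a binned / normalized matrix as CSV
#'
#' Bin centers become column headers; one row per sample.
#'
#' @param x An `nmr_binned` (or subclass).
#' @param path Output CSV path.
#' @param header Optional `#`-prefixed comment line.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, header = NULL) {
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE)
  write_csv_commented(df, path, header)
  invisible(path)
}

#' Group labels attached to a binned matrix
#' @param x An `nmr_binned` (or subclass) with metadata.
#' @return Character vector of group labels, in row order.
#' @export
group_labels <- function(x) {
  if (is.null(x$metadata) || !"group" %in% names(x$metadata)) {
    stop("no group labels in metadata", call. = FALSE)
  }
  x$metadata$group
}
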