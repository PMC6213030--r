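gauss_peak <- function(ppm, center, sd = 0.01) exp(-(ppm - center)^2 / (2 * sd^2))

test_that("TSP referencing shifts the axis so the window maximum is at 0", {
  ppm <- seq(-0.5, 2, by = 0.001)
  sp <- nmr_spectrum(ppm, gauss_peak(ppm, 0.02), "a")
  ref <- reference_to_tsp(sp, c(-0.2, 0.2))
  expect_equal(ref$ppm, sp$ppm - 0.02, tolerance = 1e-12)
  # already referenced: unchanged
  sp0 <- nmr_spectrum(ppm, gauss_peak(ppm, 0.00), "b")
  expect_equal(reference_to_tsp(sp0)$ppm, sp0$ppm)
  # flat window: warning, unchanged
  flat <- nmr_spectrum(ppm, rep(1, length(ppm)), "c")
  expect_warning(out <- reference_to_tsp(flat), "flat")
  expect_equal(out$ppm, flat$ppm)
  expect_error(reference_to_tsp(sp, c(0.1, 0.2)), "contain 0")
  short <- nmr_spectrum(seq(0, 1, by = 0.01), rep(1, 101), "d")
  expect_error(reference_to_tsp(short, c(-0.2, 0.2)), "cover")
})

test_that("cross-correlation alignment recovers a constructed offset", {
  ppm <- seq(0, 5, by = 0.001)
  base <- gauss_peak(ppm, 2) + 0.6 * gauss_peak(ppm, 3.5)
  shifted <- gauss_peak(ppm, 2.01) + 0.6 * gauss_peak(ppm, 3.51)
  spectra <- list(
    nmr_spectrum(ppm, base, "a"), nmr_spectrum(ppm, base, "b"),
    nmr_spectrum(ppm, base, "c"), nmr_spectrum(ppm, shifted, "d")
  )
  aligned <- align_spectra(spectra)
  shifts <- attr(aligned, "shifts")
  expect_equal(unname(shifts[1:3]), rep(0, 3))
  expect_lt(abs(unname(shifts[4]) + 0.01), 0.0011) # within one axis step
  expect_equal(aligned[["d"]]$intensity, base, tolerance = 0.02)

  # identical spectra align with zero shift
  same <- align_spectra(spectra[1:3])
  expect_true(all(attr(same, "shifts") == 0))

  # a larger true offset is clamped at the +/- 0.03 ppm bound
  far <- nmr_spectrum(ppm, gauss_peak(ppm, 2.08) + 0.6 * gauss_peak(ppm, 3.58), "e")
  cl <- align_spectra(list(spectra[[1]], spectra[[2]], spectra[[3]], far))
  expect_lte(max(abs(attr(cl, "shifts"))), 0.03 + 1e-9)
  expect_error(align_spectra(spectra[1]), "at least 2")
})

test_that("uniform binning yields the exact bin counts and integrals", {
  # 10 axis points per 0.015-ppm bin over the kept range
  step <- 0.0015
  # points at half-step offsets so none sits on a bin edge
  ppm <- seq(0.65 + step / 2, 9.50, by = step)
  sp <- nmr_spectrum(ppm, rep(1, length(ppm)), "const")
  bm_all <- bin_spectra(sp, excluded_regions = list())
  expect_equal(ncol(bm_all$values), 590)
  expect_true(all(bm_all$values == 10))
  bm <- bin_spectra(sp)
  expect_equal(ncol(bm$values), 563)
  expect_false(any(bm$bin_centers > 4.70 & bm$bin_centers < 5.10))
  expect_true(all(bm$bin_centers > 0.65 & bm$bin_centers < 9.50))
  # conservation without exclusions: cells sum to the spectrum total
  y <- stats::runif(length(ppm))
  bm2 <- bin_spectra(nmr_spectrum(ppm, y, "r"), excluded_regions = list())
  expect_equal(sum(bm2$values), sum(y), tolerance = 1e-9)
  # a spectrum not covering the range errors
  short_ppm <- seq(2, 9.5, by = step)
  expect_error(
    bin_spectra(nmr_spectrum(short_ppm, rep(1, length(short_ppm)), "short")),
    "cover"
  )
})

test_that("quotient normalization matches the hand-computed procedure", {
  bm <- make_binned(rbind(c(1, 2, 3), c(2, 4, 6)))
  nm <- pqn_normalize(bm, ref_quantile = 0)
  # proportional rows normalize to the same row; total factors differ 2x
  expect_equal(nm$values[1, ], nm$values[2, ], tolerance = 1e-12)
  expect_equal(
    unname(nm$dilution_factors[2] / nm$dilution_factors[1]), 2,
    tolerance = 1e-12
  )
  # stored factor maps input to output exactly
  expect_equal(
    nm$values, sweep(bm$values, 1, nm$dilution_factors, "/"),
    tolerance = 1e-12
  )
  # single sample: quotient 1, output = area-normalized input
  one <- pqn_normalize(make_binned(rbind(c(2, 3, 5))))
  expect_equal(unname(one$quotients), 1)
  expect_equal(unname(one$values[1, ]), c(2, 3, 5) / 10 * 100)
  expect_error(
    pqn_normalize(make_binned(rbind(c(1, 1), c(0, 0)))),
    "s02"
  )
})

test_that("quotient normalization recovers planted dilutions exactly when noise-free", {
  d <- clean_design(seed = 3, planted_log2fc = rep(0, 50))
  co <- simulate_cohort(d)
  nm <- pqn_normalize(bin_spectra(co$spectra, metadata = co$metadata))
  rel <- nm$dilution_factors / co$truth$dilutions
  expect_lt(max(abs(rel / mean(rel) - 1)), 1e-6)
  # idempotence: a second pass finds no residual dilution structure
  d2 <- clean_design(seed = 4) # planted effects on, still noise-free
  co2 <- simulate_cohort(d2)
  nm2 <- pqn_normalize(bin_spectra(co2$spectra, metadata = co2$metadata))
  nm3 <- pqn_normalize(nm2)
  f <- nm3$dilution_factors
  expect_lt(max(abs(f / mean(f) - 1)), 1e-9)
})

test_that("Pareto scaling centers, divides by sqrt(sd) and inverts", {
  bm <- make_binned(rbind(c(1, 5, 2), c(2, 5, 4), c(3, 5, 9)))
  sc <- pareto_scale(bm)
  expect_equal(unname(sc$values[, 1]), c(-1, 0, 1)) # sd 1, sqrt 1
  expect_true(sc$zero_variance[2])
  expect_equal(unname(sc$values[, 2]), c(0, 0, 0))
  expect_true(all(abs(colMeans(sc$values)) < 1e-10))
  expect_equal(pareto_unscale(sc), bm$values, tolerance = 1e-10)
  expect_error(pareto_scale(make_binned(rbind(c(1, 2)))), ">= 2 samples")
})

test_that("asymmetric-least-squares baseline removal recovers a planted drift", {
  ppm <- seq(0.65, 9.50, length.out = 4096)
  drift <- 0.5 * (1 + sin(2 * pi * ppm / 8.85 + 1))
  peaks <- 10 * gauss_peak(ppm, 2, 0.01) + 8 * gauss_peak(ppm, 7, 0.01)
  sp <- nmr_spectrum(ppm, peaks + drift, "drifty")
  corrected <- baseline_correct(sp)
  # off-peak residual drift several-fold smaller than the raw drift level
  off_peak <- abs(ppm - 2) > 0.2 & abs(ppm - 7) > 0.2
  expect_lt(
    stats::median(abs(corrected$intensity[off_peak])),
    stats::median(drift[off_peak]) / 4
  )
  # peak heights survive
  expect_gt(max(corrected$intensity[abs(ppm - 2) < 0.05]), 9)
})
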