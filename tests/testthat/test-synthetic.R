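test_that("peak library respects the observable window and is reproducible", {
  lib <- default_metabolite_library(50, seed = 1)
  expect_length(unique(lib$metabolite), 50)
  expect_true(all(lib$center >= 0.65 & lib$center <= 9.50))
  expect_true(all(lib$center < 4.70 | lib$center > 5.10))
  expect_true(all(lib$halfwidth > 0))
  # 1-4 peaks per metabolite bounds the total
  expect_gte(nrow(lib), 50)
  expect_lte(nrow(lib), 200)
  counts <- table(lib$metabolite)
  expect_true(all(counts >= 1 & counts <= 4))
  expect_identical(
    default_metabolite_library(1, seed = 7),
    default_metabolite_library(1, seed = 7)
  )
  expect_error(default_metabolite_library(0), "n_metabolites")
})

test_that("simulated spectrum follows the Lorentzian mixture model", {
  # axis chosen so delta = 1.00 is an exact grid point
  lib <- tibble::tibble(
    metabolite = "metA", center = 1.00, height = 1, halfwidth = 0.005
  )
  design <- cohort_design(
    library = lib, concentration_cv = 0, noise_sd = 0,
    baseline_amplitude = 0, shift_jitter_sd = 0, water_artifact = FALSE,
    n_points = 3541, seed = 1
  )
  sp <- simulate_spectrum(design, c(metA = 2), dilution = 1.5, seed = 1)
  at_center <- sp$intensity[which.min(abs(sp$ppm - 1.00))]
  expect_equal(at_center, 1.5 * 2 * 1, tolerance = 1e-12)

  # empty mixture gives the zero spectrum
  sp0 <- simulate_spectrum(design, c(metA = 0), dilution = 1, seed = 1)
  expect_true(all(sp0$intensity == 0))

  # intensity is exactly linear in dilution under a fixed seed
  d2 <- cohort_design(
    library = default_metabolite_library(5, seed = 2),
    noise_sd = 0, baseline_amplitude = 0, water_artifact = FALSE,
    n_points = 2048, seed = 2
  )
  conc <- stats::setNames(rep(1, 5), d2$metabolites)
  s1 <- simulate_spectrum(d2, conc, 1, seed = 9)
  s2 <- simulate_spectrum(d2, conc, 2, seed = 9)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)

  expect_error(simulate_spectrum(d2, -conc, 1, seed = 1), "non-negative")
  expect_error(simulate_spectrum(d2, conc, 0, seed = 1), "positive")
})

test_that("cohorts have the declared structure and exact planted effects", {
  d <- cohort_design(
    library = separated_library(4),
    n_terrestrial = 6, n_marine = 18,
    planted_log2fc = c(1, 0, 0, 0),
    concentration_cv = 0, dilution_range = c(1, 1),
    noise_sd = 0, baseline_amplitude = 0, shift_jitter_sd = 0,
    water_artifact = FALSE, n_points = 1024, seed = 4
  )
  co <- simulate_cohort(d)
  expect_length(co$spectra, 24)
  expect_equal(nrow(co$metadata), 24)
  expect_equal(sum(co$metadata$group == "marine"), 18)
  expect_equal(sort(unique(co$metadata$strain)),
    c("Land", "Marine-1", "Marine-2", "Marine-3"))
  # planted log2FC = 1 with zero CV: group mean ratio exactly 2
  g <- co$metadata$group
  m <- co$truth$concentrations[, "met01"]
  expect_equal(mean(m[g == "marine"]) / mean(m[g == "terrestrial"]), 2)
  expect_identical(co$truth$differential, "met01")

  # no planted effect, empty differential set
  d0 <- cohort_design(
    library = separated_library(4), planted_log2fc = rep(0, 4),
    n_points = 512, seed = 5
  )
  expect_length(simulate_cohort(d0)$truth$differential, 0)
})

test_that("cohort generation is deterministic for a fixed design", {
  d <- cohort_design(
    library = separated_library(3), n_points = 512, seed = 11
  )
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$truth$concentrations, c2$truth$concentrations)
  expect_identical(
    lapply(c1$spectra, function(s) s$intensity),
    lapply(c2$spectra, function(s) s$intensity)
  )
})

test_that("ground-truth annotation picks an in-range window per metabolite", {
  co <- default_cohort()
  ann <- annotation_from_truth(co$truth)
  expect_setequal(unique(ann$metabolite), co$truth$design$metabolites)
  expect_true(all(ann$ppm_high > ann$ppm_low))
  pair <- stocsy_pair_from_truth(co$truth)
  expect_equal(nrow(pair), 2)
  expect_equal(pair$metabolite[1], pair$metabolite[2])
  # distinct bins for driver and sibling
  expect_false(
    floor((pair$center[1] - 0.65) / 0.015) ==
      floor((pair$center[2] - 0.65) / 0.015)
  )
})

test_that("cohort export writes spectra, metadata and ground truth", {
  d <- cohort_design(library = separated_library(3), n_points = 512, seed = 6)
  co <- simulate_cohort(d)
  out <- withr::local_tempdir()
  write_cohort(co, out)
  expect_true(file.exists(file.path(out, "spectra.csv")))
  expect_true(file.exists(file.path(out, "metadata.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  back <- read_cohort_csv(file.path(out, "spectra.csv"))
  expect_length(back, 24)
  expect_equal(back[[1]]$intensity, co$spectra[[1]]$intensity,
    tolerance = 1e-6
  )
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"))
  expect_named(truth, c("dilutions", "concentrations", "differential", "peaks"))
})
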