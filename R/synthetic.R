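#' Generate a default metabolite peak library
#'
#' Builds a library of synthetic metabolite peak patterns mimicking the
#' multiplet structure of small-molecule 1H resonances: each metabolite has
#' 1-4 Lorentzian peaks with centers in the observable window
#' \eqn{\delta} 0.65-9.50 ppm, excluding the residual-water region
#' (4.70, 5.10). Extra peaks of a metabolite are placed either adjacent to
#' an anchor resonance (a multiplet) or elsewhere in the window (a distinct
#' proton group).
#'
#' @param n_metabolites Number of metabolites (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param halfwidth Lorentzian half-width at half-maximum (ppm) for every
#'   peak. The default 0.003 ppm gives peaks spanning several 0.015-ppm
#'   bins.
#' @return A tibble of class `metabolite_library` with one row per peak:
#'   columns `metabolite`, `center` (ppm), `height` (relative, unitless),
#'   `halfwidth` (ppm).
#' @export
#' @examples
#' lib <- default_metabolite_library(10, seed = 1)
#' dplyr::count(lib, metabolite)
default_metabolite_library <- function(n_metabolites = 50, seed = 1,
                                       halfwidth = 0.003) {
  if (!is.numeric(n_metabolites) || n_metabolites < 1) {
    stop("`n_metabolites` must be >= 1", call. = FALSE)
  }
  n_metabolites <- as.integer(n_metabolites)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_metabolites), function(m) {
      n_peaks <- sample.int(4L, 1L)
      anchor <- draw_center()
      centers <- anchor
      if (n_peaks > 1L) {
        for (k in seq_len(n_peaks - 1L)) {
          c_new <- if (stats::runif(1) < 0.5) {
            # sibling resonance of the same multiplet
            nudge_center(anchor + stats::runif(1, -0.03, 0.03))
          } else {
            draw_center()
          }
          centers <- c(centers, c_new)
        }
      }
      tibble::tibble(
        metabolite = sprintf("met%02d", m),
        center = centers,
        height = stats::runif(n_peaks, 0.3, 1),
        halfwidth = halfwidth
      )
    })
    lib <- dplyr::bind_rows(rows)
  })
  class(lib) <- c("metabolite_library", class(lib))
  lib
}

# Uniform draw over [0.65, 4.70) U (5.10, 9.50]
draw_center <- function() {
  w1 <- 4.70 - 0.65
  w2 <- 9.50 - 5.10
  u <- stats::runif(1, 0, w1 + w2)
  if (u < w1) 0.65 + u else 5.10 + (u - w1)
}

# Push a proposed center back inside the allowed window
nudge_center <- function(x) {
  if (x < 0.65) return(0.65 + (0.65 - x))
  if (x > 9.50) return(9.50 - (x - 9.50))
  if (x > 4.70 && x < 5.10) return(if (x < 4.90) 4.70 - (x - 4.70) else 5.10 + (5.10 - x))
  x
}

#' Describe a two-group synthetic NMR cohort
#'
#' Collects every parameter of the simulated study: the peak library,
#' group sizes (default 6 terrestrial vs 18 marine, i.e. one terrestrial
#' strain and three marine strains with 6 replicate cultures each),
#' per-metabolite baseline concentrations, planted between-group effects,
#' biological variation, per-sample dilution, peak-position jitter,
#' baseline drift, additive noise and the residual-water artifact.
#'
#' Planted effects follow the convention log2(fold change) of the marine
#' group relative to the terrestrial group; the default plants
#' |log2FC| = 1 on 10 of the metabolites (5 up in marine, 5 down).
#'
#' @param library A `metabolite_library`; defaults to
#'   [default_metabolite_library()] with 50 metabolites drawn under `seed`.
#' @param n_terrestrial,n_marine Group sizes (each >= 2).
#' @param base_concentration Per-metabolite mean concentration in the
#'   terrestrial group (unitless). Default: log-normal draws (sdlog 0.4)
#'   around 1 under `seed`.
#' @param planted_log2fc Per-metabolite planted effect (log2 units, marine
#'   relative to terrestrial). Default: +1 for the first 5 metabolites,
#'   -1 for the next 5, 0 elsewhere.
#' @param concentration_cv Within-group coefficient of variation of true
#'   concentrations (log-normal biology). Default 0.15.
#' @param dilution_range Two-element vector, multiplicative per-sample
#'   dilution drawn uniformly; low bound must be > 0. Default c(0.5, 2).
#' @param shift_jitter_sd SD (ppm) of per-peak chemical-shift jitter.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param baseline_amplitude Amplitude of the slow sinusoidal baseline
#'   drift (intensity units).
#' @param water_artifact Logical; add a broad residual-water Lorentzian
#'   (center 4.90 ppm, half-width 0.08 ppm, random amplitude per sample)?
#' @param water_region Ppm interval of the artifact, default c(4.70, 5.10).
#' @param ppm_range Observable window, default c(0.65, 9.50).
#' @param n_points Number of uniform axis points, default 16384.
#' @param seed Integer master seed for the cohort.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(library = NULL,
                          n_terrestrial = 6, n_marine = 18,
                          base_concentration = NULL,
                          planted_log2fc = NULL,
                          concentration_cv = 0.15,
                          dilution_range = c(0.5, 2),
                          shift_jitter_sd = 0.001,
                          noise_sd = 0.005,
                          baseline_amplitude = 0.01,
                          water_artifact = TRUE,
                          water_region = c(4.70, 5.10),
                          ppm_range = c(0.65, 9.50),
                          n_points = 16384,
                          seed = 1) {
  if (n_terrestrial < 2 || n_marine < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (dilution_range[1] <= 0 || diff(dilution_range) < 0) {
    stop("`dilution_range` must be positive and ordered", call. = FALSE)
  }
  if (concentration_cv < 0) stop("`concentration_cv` must be >= 0", call. = FALSE)
  if (is.null(library)) library <- default_metabolite_library(50, seed = seed)
  metabolites <- unique(library$metabolite)
  n_met <- length(metabolites)
  if (is.null(base_concentration)) {
    base_concentration <- withr::with_seed(
      seed + 101L,
      stats::rlnorm(n_met, meanlog = 0, sdlog = 0.4)
    )
  }
  base_concentration <- stats::setNames(rep_len(base_concentration, n_met), metabolites)
  if (is.null(planted_log2fc)) {
    planted_log2fc <- numeric(n_met)
    n_up <- min(5L, n_met)
    n_dn <- min(5L, max(0L, n_met - 5L))
    planted_log2fc[seq_len(n_up)] <- 1
    if (n_dn > 0) planted_log2fc[n_up + seq_len(n_dn)] <- -1
  }
  planted_log2fc <- stats::setNames(rep_len(planted_log2fc, n_met), metabolites)
  structure(
    list(
      library = library,
      metabolites = metabolites,
      n_terrestrial = as.integer(n_terrestrial),
      n_marine = as.integer(n_marine),
      base_concentration = base_concentration,
      planted_log2fc = planted_log2fc,
      concentration_cv = concentration_cv,
      dilution_range = dilution_range,
      shift_jitter_sd = shift_jitter_sd,
      noise_sd = noise_sd,
      baseline_amplitude = baseline_amplitude,
      water_artifact = isTRUE(water_artifact),
      water_region = water_region,
      ppm_range = ppm_range,
      n_points = as.integer(n_points),
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_design> %d metabolites (%d peaks), %d terrestrial vs ",
      "%d marine\n  %d differential (|log2FC| > 0), CV %.2f, dilution ",
      "U(%.2g, %.2g), seed %d\n"
    ),
    length(x$metabolites), nrow(x$library), x$n_terrestrial, x$n_marine,
    sum(x$planted_log2fc != 0), x$concentration_cv,
    x$dilution_range[1], x$dilution_range[2], x$seed
  ))
  invisible(x)
}

# Lorentzian mixture evaluated on an axis: sum_k amp_k w^2/((x-c_k)^2+w^2)
lorentzian_mixture <- function(ppm, centers, amplitudes, halfwidths) {
  keep <- amplitudes != 0
  if (!any(keep)) return(numeric(length(ppm)))
  centers <- centers[keep]
  amplitudes <- amplitudes[keep]
  halfwidths <- halfwidths[keep]
  d <- outer(ppm, centers, "-")
  w2 <- matrix(halfwidths^2, nrow = length(ppm), ncol = length(centers), byrow = TRUE)
  as.numeric((w2 / (d * d + w2)) %*% amplitudes)
}

#' Simulate a single 1H NMR spectrum
#'
#' Evaluates the Lorentzian mixture implied by the design's peak library
#' at the supplied true concentrations, scaled by a multiplicative
#' dilution factor, and adds per-peak chemical-shift jitter, a slow
#' sinusoidal baseline, Gaussian noise and (optionally) the residual-water
#' artifact. The water artifact does not scale with dilution: it is a
#' solvent feature, not an analyte.
#'
#' @param design A [cohort_design()].
#' @param concentrations Named (or design-ordered) non-negative vector of
#'   true metabolite concentrations.
#' @param dilution Positive multiplicative dilution factor.
#' @param seed Integer seed for jitter/noise/baseline/artifact draws.
#' @param sample_id Sample label.
#' @return An [nmr_spectrum()] on a uniform axis over `design$ppm_range`.
#' @export
simulate_spectrum <- function(design, concentrations, dilution, seed,
                              sample_id = "sample") {
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (dilution <= 0) stop("`dilution` must be positive", call. = FALSE)
  if (is.null(names(concentrations))) {
    names(concentrations) <- design$metabolites
  }
  lib <- design$library
  conc <- concentrations[lib$metabolite]
  ppm <- seq(design$ppm_range[1], design$ppm_range[2],
    length.out = design$n_points
  )
  withr::with_seed(seed, {
    eps <- stats::rnorm(nrow(lib), 0, design$shift_jitter_sd)
    signal <- lorentzian_mixture(
      ppm, lib$center + eps, dilution * conc * lib$height, lib$halfwidth
    )
    baseline <- if (design$baseline_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      design$baseline_amplitude *
        (1 + sin(2 * pi * ppm / diff(design$ppm_range) + phase)) / 2
    } else {
      numeric(length(ppm))
    }
    water <- if (design$water_artifact) {
      amp <- stats::runif(1, 0.5, 2)
      lorentzian_mixture(ppm, mean(design$water_region), amp, 0.08)
    } else {
      numeric(length(ppm))
    }
    noise <- if (design$noise_sd > 0) {
      stats::rnorm(length(ppm), 0, design$noise_sd)
    } else {
      numeric(length(ppm))
    }
  })
  nmr_spectrum(ppm, signal + baseline + water + noise, sample_id)
}

#' Simulate a full two-group cohort with ground truth
#'
#' Draws per-sample true concentrations log-normally around the group
#' means (terrestrial mean = `base_concentration`; marine mean =
#' `base_concentration * 2^planted_log2fc`) with coefficient of variation
#' `concentration_cv`, per-sample dilution factors uniformly over
#' `dilution_range`, and renders each sample's spectrum with
#' [simulate_spectrum()]. Everything needed to score downstream stages is
#' recorded in the returned ground truth.
#'
#' @param design A [cohort_design()].
#' @return A list of class `nmr_cohort` with elements `spectra` (named
#'   list of [nmr_spectrum()]), `metadata` (tibble: sample_id, strain,
#'   group, medium), and `truth` (list of class `cohort_truth`:
#'   `dilutions`, `concentrations` samples-by-metabolites matrix,
#'   `differential` character vector, `peaks` the peak->metabolite map,
#'   `design` the design used).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_design(seed = 1, n_points = 2048))
#' cohort$metadata
#' }
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_terrestrial + design$n_marine
  metabolites <- design$metabolites
  n_met <- length(metabolites)

  # strain labels: terrestrial "Land"; marine split into 3 strains when the
  # group size divides evenly (the study's 3 marine isolates), else one
  marine_strains <- if (design$n_marine %% 3L == 0L) {
    rep(sprintf("Marine-%d", 1:3), each = design$n_marine / 3L)
  } else {
    rep("Marine-1", design$n_marine)
  }
  metadata <- tibble::tibble(
    sample_id = c(
      sprintf("Land_%02d", seq_len(design$n_terrestrial)),
      sprintf(
        "%s_%02d", marine_strains,
        unlist(lapply(
          rle(marine_strains)$lengths, seq_len
        ))
      )
    ),
    strain = c(rep("Land", design$n_terrestrial), marine_strains),
    group = c(
      rep("terrestrial", design$n_terrestrial),
      rep("marine", design$n_marine)
    ),
    medium = "M3"
  )

  cv <- design$concentration_cv
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(design$seed, {
    group_mean <- rbind(
      terrestrial = design$base_concentration,
      marine = design$base_concentration * 2^design$planted_log2fc
    )
    conc <- matrix(0, n, n_met, dimnames = list(metadata$sample_id, metabolites))
    for (i in seq_len(n)) {
      mu <- group_mean[metadata$group[i], ]
      conc[i, ] <- if (cv > 0) {
        stats::rlnorm(n_met, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        mu
      }
    }
    dilutions <- stats::setNames(
      stats::runif(n, design$dilution_range[1], design$dilution_range[2]),
      metadata$sample_id
    )
    spectrum_seeds <- sample.int(2147483646L, n)
  })
  spectra <- lapply(seq_len(n), function(i) {
    simulate_spectrum(
      design, conc[i, ], dilutions[i], spectrum_seeds[i],
      sample_id = metadata$sample_id[i]
    )
  })
  names(spectra) <- metadata$sample_id

  truth <- structure(
    list(
      dilutions = dilutions,
      concentrations = conc,
      differential = metabolites[design$planted_log2fc != 0],
      peaks = design$library,
      design = design
    ),
    class = "cohort_truth"
  )
  structure(
    list(spectra = spectra, metadata = metadata, truth = truth),
    class = "nmr_cohort"
  )
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat(sprintf(
    "<nmr_cohort> %d spectra (%d terrestrial, %d marine), %d metabolites\n",
    length(x$spectra), sum(x$metadata$group == "terrestrial"),
    sum(x$metadata$group == "marine"),
    ncol(x$truth$concentrations)
  ))
  invisible(x)
}

#' Integration windows from simulation ground truth
#'
#' Builds an annotation map (metabolite -> ppm windows) from the true
#' peak positions of a simulated cohort. Mirroring how an analyst picks
#' an isolated resonance to integrate in a crowded spectrum, each
#' metabolite is quantified on the peak whose integration window has the
#' smallest estimated share of foreign signal: for every peak, the
#' Lorentzian integrals of all other metabolites' peaks over the window
#' (weighted by their expected amplitudes, concentration x height) are
#' summed and divided by the peak's own expected integral; the peak
#' minimizing this contamination ratio wins. One window of
#' `2 * half_window` ppm is centered on the chosen peak.
#'
#' @param truth A `cohort_truth` (from [simulate_cohort()]).
#' @param half_window Half-width of each integration window (ppm);
#'   default half a bin width (0.0075).
#' @param all_peaks Use every peak instead of the least contaminated one
#'   (windows will overlap more between metabolites).
#' @return An annotation tibble with columns `metabolite`, `ppm_low`,
#'   `ppm_high` (class `annotation_map`).
#' @export
annotation_from_truth <- function(truth, half_window = 0.0075,
                                  all_peaks = FALSE) {
  peaks <- truth$peaks
  design <- truth$design
  # expected amplitude per peak, averaged over the two group means
  conc <- design$base_concentration[peaks$metabolite] *
    (1 + 2^design$planted_log2fc[peaks$metabolite]) / 2
  amp <- conc * peaks$height
  # fraction of a unit Lorentzian (center c, halfwidth w) falling in a
  # window of half-width h around x0
  win_frac <- function(c0, w, x0, h) {
    (atan((x0 + h - c0) / w) - atan((x0 - h - c0) / w)) / pi
  }
  if (all_peaks) {
    sel <- peaks
  } else {
    sel <- peaks |>
      dplyr::mutate(.amp = amp) |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::group_modify(function(p, key) {
        foreign <- peaks$metabolite != key$metabolite
        contamination <- vapply(seq_len(nrow(p)), function(i) {
          own <- p$.amp[i] * p$halfwidth[i] *
            win_frac(p$center[i], p$halfwidth[i], p$center[i], half_window)
          other <- sum(amp[foreign] * peaks$halfwidth[foreign] *
            win_frac(
              peaks$center[foreign], peaks$halfwidth[foreign],
              p$center[i], half_window
            ))
          other / own
        }, numeric(1))
        p[order(contamination, -p$.amp)[1], , drop = FALSE]
      }) |>
      dplyr::ungroup() |>
      dplyr::select(-".amp")
  }
  ann <- tibble::tibble(
    metabolite = sel$metabolite,
    ppm_low = sel$center - half_window,
    ppm_high = sel$center + half_window
  )
  class(ann) <- c("annotation_map", class(ann))
  ann
}

#' Pick a clean two-peak metabolite for STOCSY demonstrations
#'
#' Among metabolites with at least two resonances falling in different
#' bins, selects the one whose two least-contaminated peaks (estimated
#' foreign signal share, as in [annotation_from_truth()]) are cleanest,
#' and returns those two peaks: a driver and its sibling. Driving STOCSY
#' on one should light up the other, since both report the same
#' underlying concentration.
#'
#' @param truth A `cohort_truth`.
#' @param bin_width Bin width used downstream (default 0.015 ppm).
#' @param half_window Contamination window half-width (default 0.0075).
#' @return Two-row tibble (driver first) with `metabolite`, `center`,
#'   `contamination`.
#' @export
stocsy_pair_from_truth <- function(truth, bin_width = 0.015,
                                   half_window = 0.0075) {
  peaks <- truth$peaks
  design <- truth$design
  conc <- design$base_concentration[peaks$metabolite] *
    (1 + 2^design$planted_log2fc[peaks$metabolite]) / 2
  amp <- conc * peaks$height
  win_frac <- function(c0, w, x0, h) {
    (atan((x0 + h - c0) / w) - atan((x0 - h - c0) / w)) / pi
  }
  contamination <- vapply(seq_len(nrow(peaks)), function(i) {
    foreign <- peaks$metabolite != peaks$metabolite[i]
    own <- amp[i] * peaks$halfwidth[i] *
      win_frac(peaks$center[i], peaks$halfwidth[i], peaks$center[i], half_window)
    sum(amp[foreign] * peaks$halfwidth[foreign] *
      win_frac(
        peaks$center[foreign], peaks$halfwidth[foreign],
        peaks$center[i], half_window
      )) / own
  }, numeric(1))
  peaks$contamination <- contamination
  # binning starts at the lower edge of the kept range (0.65), not at the
  # simulation range, when they differ; the default has them equal
  bin_origin <- design$ppm_range[1]
  offset <- (peaks$center - bin_origin) / bin_width
  peaks$bin_index <- floor(offset)
  # distance of the peak from the nearest bin edge, in ppm: shift jitter
  # redistributes intensity across the edge, so centered peaks give the
  # cleanest single-bin readout
  peaks$edge_dist <- bin_width * pmin(offset - peaks$bin_index,
    1 - (offset - peaks$bin_index)
  )
  candidates <- list()
  for (m in unique(peaks$metabolite)) {
    p <- peaks[peaks$metabolite == m, , drop = FALSE]
    p <- p[order(p$contamination), , drop = FALSE]
    p <- p[!duplicated(p$bin_index), , drop = FALSE]
    if (nrow(p) < 2) next
    # two cleanest peaks in distinct bins, driver = better-centered one
    pair <- p[1:2, , drop = FALSE]
    pair <- pair[order(-pair$edge_dist), , drop = FALSE]
    candidates[[m]] <- pair
  }
  if (length(candidates) == 0) {
    stop("no metabolite with two resolvable peaks found", call. = FALSE)
  }
  clean <- Filter(function(p) max(p$contamination) <= 0.05, candidates)
  pool <- if (length(clean)) clean else candidates
  worst_edge <- vapply(pool, function(p) min(p$edge_dist), numeric(1))
  best <- pool[[which.max(worst_edge)]]
  best[, c("metabolite", "center", "contamination", "edge_dist")]
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample two-column ASCII spectra, a cohort samples-by-ppm CSV,
#' a metadata CSV and the ground truth as JSON.
#'
#' @param cohort An `nmr_cohort`.
#' @param outdir Output directory (created if needed).
#' @param header Optional comment written at the top of each CSV.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir, header = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec_dir <- file.path(outdir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  for (s in cohort$spectra) {
    write_spectrum(s, file.path(spec_dir, paste0(sample_id(s), ".txt")))
  }
  write_cohort_csv(cohort$spectra, file.path(outdir, "spectra.csv"), header)
  write_csv_commented(cohort$metadata, file.path(outdir, "metadata.csv"), header)
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      dilutions = as.list(truth$dilutions),
      concentrations = list(
        sample_id = rownames(truth$concentrations),
        metabolite = colnames(truth$concentrations),
        values = unname(apply(truth$concentrations, 1, as.list))
      ),
      differential = truth$differential,
      peaks = truth$peaks
    ),
    file.path(outdir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}
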