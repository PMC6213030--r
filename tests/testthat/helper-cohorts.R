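# Shared fixtures, built in code and cached per test session.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

# the default study-design cohort (6 terrestrial vs 18 marine, 50
# metabolites, 10 planted at |log2FC| = 1)
default_cohort <- function(seed = 1) {
  cached(paste0("default", seed), simulate_cohort(cohort_design(seed = seed)))
}

# artifact-free design: no biological CV, no noise, no baseline, no
# jitter, no water artifact
clean_design <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, concentration_cv = 0, noise_sd = 0,
      baseline_amplitude = 0, shift_jitter_sd = 0, water_artifact = FALSE
    ),
    list(...)
  )
  do.call(cohort_design, args)
}

# normalized matrix of the default cohort via the standard preprocessing
# chain (baseline correction -> binning -> quotient normalization)
default_normalized <- function(seed = 1) {
  cached(paste0("norm", seed), {
    co <- default_cohort(seed)
    pqn_normalize(bin_spectra(
      baseline_correct(co$spectra),
      metadata = co$metadata
    ))
  })
}

# hand-built binned matrix for unit tests of normalization/scaling
make_binned <- function(values, centers = NULL, groups = NULL) {
  values <- as.matrix(values)
  if (is.null(centers)) centers <- seq_len(ncol(values))
  ids <- sprintf("s%02d", seq_len(nrow(values)))
  rownames(values) <- ids
  colnames(values) <- as.character(centers)
  metadata <- if (is.null(groups)) {
    NULL
  } else {
    tibble::tibble(sample_id = ids, group = groups)
  }
  structure(
    list(
      values = values, bin_centers = centers,
      bin_width = if (length(centers) > 1) diff(centers)[1] else 1,
      kept_range = range(centers) + c(-0.5, 0.5),
      excluded_regions = list(),
      sample_ids = ids, metadata = metadata
    ),
    class = "nmr_binned"
  )
}

# a small library of well-separated single/double peaks for tests that
# need contamination-free quantification
separated_library <- function(n = 8, two_peak = integer(0)) {
  centers <- seq(1.0, 9.0, length.out = n)
  centers <- centers[centers < 4.5 | centers > 5.3]
  n <- length(centers)
  rows <- lapply(seq_len(n), function(i) {
    cc <- centers[i]
    if (i %in% two_peak) cc <- c(cc, cc + 0.2)
    tibble::tibble(
      metabolite = sprintf("met%02d", i),
      center = cc, height = 1, halfwidth = 0.003
    )
  })
  lib <- dplyr::bind_rows(rows)
  class(lib) <- c("metabolite_library", class(lib))
  lib
}
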