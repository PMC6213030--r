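#' Pipeline configuration
#'
#' Collects every knob of a full run. With `synthetic = TRUE` (the
#' default) the input cohort is simulated from `design`; otherwise
#' `spectra` (directory of two-column ASCII files or a samples-by-ppm
#' CSV), `metadata_csv` and `annotation_csv` must point to existing
#' files.
#'
#' @param synthetic Simulate the input cohort?
#' @param design A [cohort_design()] used when `synthetic` (its seed is
#'   overridden by the derived stage seed).
#' @param spectra,metadata_csv,annotation_csv Input paths for real data.
#' @param baseline_correction Apply [baseline_correct()] to every
#'   spectrum before binning (default TRUE)?
#' @param bin_width,kept_range,excluded_regions Binning parameters, see
#'   [bin_spectra()].
#' @param n_components,n_folds,n_permutations Model parameters.
#' @param thresholds A [threshold_config()].
#' @param network_threshold Strict |r| cutoff for networks (default 0.6).
#' @param bin_alpha Significance level for the loading-profile |r|
#'   cutoff (default 0.05).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            design = NULL,
                            spectra = NULL,
                            metadata_csv = NULL,
                            annotation_csv = NULL,
                            baseline_correction = TRUE,
                            bin_width = 0.015,
                            kept_range = c(0.65, 9.50),
                            excluded_regions = list(c(4.70, 5.10)),
                            n_components = 2,
                            n_folds = 7,
                            n_permutations = 200,
                            thresholds = threshold_config(),
                            network_threshold = 0.6,
                            bin_alpha = 0.05,
                            seed = 1) {
  cfg <- structure(
    list(
      synthetic = isTRUE(synthetic), design = design,
      spectra = spectra, metadata_csv = metadata_csv,
      annotation_csv = annotation_csv,
      baseline_correction = isTRUE(baseline_correction),
      bin_width = bin_width, kept_range = kept_range,
      excluded_regions = excluded_regions,
      n_components = n_components, n_folds = n_folds,
      n_permutations = n_permutations,
      thresholds = thresholds,
      network_threshold = network_threshold,
      bin_alpha = bin_alpha,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!cfg$synthetic) {
    for (p in c(cfg$spectra, cfg$metadata_csv, cfg$annotation_csv)) {
      if (is.null(p)) {
        stop("non-synthetic runs need spectra, metadata_csv and annotation_csv",
          call. = FALSE
        )
      }
      if (!file.exists(p)) {
        stop(sprintf("input path does not exist: %s", p), call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `design` block is passed to [cohort_design()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$excluded_regions)) {
    raw$excluded_regions <- lapply(
      if (is.list(raw$excluded_regions)) raw$excluded_regions
      else list(raw$excluded_regions),
      as.numeric
    )
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(threshold_config, raw$thresholds)
  }
  if (!is.null(raw$design)) {
    raw$design <- do.call(cohort_design, raw$design)
  }
  do.call(pipeline_config, raw)
}

# deterministic per-stage seed derived from the master seed
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131071 + k * 9973) %% 2147483647)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Run the full comparative-metabolomics pipeline
#'
#' Executes simulate/ingest -> preprocess (bin, quotient-normalize,
#' Pareto-scale) -> PCA -> PLS-DA with permutation validation ->
#' metabolite quantification -> univariate testing -> characteristic
#' intersection -> group correlation networks, writing every stage's
#' output under `outdir`. All CSV/JSON outputs carry the config hash and
#' are byte-reproducible under a fixed seed; `run.log` records wall-clock
#' timings and is the only non-deterministic file.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created; existing files overwritten).
#' @param verbose Print a line per stage?
#' @return `outdir`, invisibly. A `manifest.json` in it lists the stages
#'   run, the seed, the config hash and headline numbers.
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- sprintf("metabonmr config=%s seed=%d", hash, config$seed)
  log_path <- file.path(outdir, "run.log")
  cat(sprintf("# run %s\n", hdr), file = log_path)
  stages <- character(0)
  t_all <- Sys.time()
  log_stage <- function(name, detail) {
    dt <- as.numeric(Sys.time() - t_all, units = "secs")
    line <- sprintf("[%7.2fs] %-12s %s", dt, name, detail)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
    stages <<- c(stages, name)
  }
  fail <- function(name, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  }

  # -- stage 1: simulate or ingest -----------------------------------
  truth <- NULL
  tryCatch({
    if (config$synthetic) {
      design <- config$design %||% cohort_design(seed = config$seed)
      design$seed <- stage_seed(config$seed, 1L)
      cohort <- simulate_cohort(design)
      spectra <- cohort$spectra
      metadata <- cohort$metadata
      truth <- cohort$truth
      annotation <- annotation_from_truth(truth)
      write_cohort(cohort, file.path(outdir, "cohort"), header = hdr)
    } else {
      spectra <- if (dir.exists(config$spectra)) {
        files <- sort(list.files(config$spectra, full.names = TRUE))
        stats::setNames(
          lapply(files, read_spectrum),
          sub("\\.[^.]*$", "", basename(files))
        )
      } else {
        read_cohort_csv(config$spectra)
      }
      metadata <- tibble::as_tibble(
        utils::read.csv(config$metadata_csv, comment.char = "#")
      )
      annotation <- read_annotation(config$annotation_csv)
    }
    log_stage("ingest", sprintf("%d spectra", length(spectra)))
  }, error = function(e) fail("ingest", e))

  # -- stage 2: preprocess -------------------------------------------
  tryCatch({
    if (config$baseline_correction) spectra <- baseline_correct(spectra)
    binned <- bin_spectra(
      spectra, config$bin_width, config$kept_range,
      config$excluded_regions, metadata
    )
    normalized <- pqn_normalize(binned)
    scaled <- pareto_scale(normalized)
    write_matrix_csv(binned, file.path(outdir, "binned.csv"), hdr)
    write_matrix_csv(normalized, file.path(outdir, "normalized.csv"), hdr)
    log_stage("preprocess", sprintf(
      "%d x %d bins", nrow(binned$values), ncol(binned$values)
    ))
  }, error = function(e) fail("preprocess", e))

  # -- stage 3: PCA ---------------------------------------------------
  tryCatch({
    pca <- nmr_pca(scaled, config$n_components)
    write_csv_commented(
      data.frame(sample_id = rownames(pca$scores), pca$scores,
        check.names = FALSE
      ),
      file.path(outdir, "pca_scores.csv"), hdr
    )
    write_csv_commented(
      data.frame(bin = format_ppm(pca$bin_centers), pca$loadings,
        check.names = FALSE
      ),
      file.path(outdir, "pca_loadings.csv"), hdr
    )
    log_stage("pca", sprintf(
      "PC1 %.1f%%", 100 * pca$explained_variance_fraction[1]
    ))
  }, error = function(e) fail("pca", e))

  # -- stage 4: PLS-DA + permutations --------------------------------
  tryCatch({
    groups <- metadata$group
    model <- plsda(scaled, groups, config$n_components)
    perm <- plsda_permutation(
      normalized, groups, config$n_components, config$n_folds,
      config$n_permutations, stage_seed(config$seed, 4L)
    )
    profile <- loading_profile(model, scaled, groups)
    write_csv_commented(
      data.frame(sample_id = rownames(model$scores), model$scores,
        check.names = FALSE
      ),
      file.path(outdir, "plsda_scores.csv"), hdr
    )
    write_csv_commented(
      as.data.frame(profile),
      file.path(outdir, "plsda_loading_profile.csv"), hdr
    )
    write_csv_commented(
      data.frame(
        permutation = seq_len(perm$n_permutations),
        R2Y = perm$permuted_R2Y, Q2 = perm$permuted_Q2
      ),
      file.path(outdir, "plsda_permutations.csv"), hdr
    )
    jsonlite::write_json(
      list(
        config = hash, seed = config$seed,
        n_components = config$n_components,
        R2X = model$R2X, R2Y = model$R2Y,
        Q2 = perm$observed_Q2, permutation_p_Q2 = perm$empirical_p_Q2
      ),
      file.path(outdir, "plsda_model.json"),
      auto_unbox = TRUE, digits = NA
    )
    log_stage("plsda", sprintf(
      "R2Y %.3f Q2 %.3f p %.4f", model$R2Y, perm$observed_Q2,
      perm$empirical_p_Q2
    ))
  }, error = function(e) fail("plsda", e))

  # -- stage 5: quantify ---------------------------------------------
  tryCatch({
    met_table <- quantify_metabolites(normalized, annotation)
    write_csv_commented(
      as.data.frame(met_table), file.path(outdir, "metabolite_table.csv"), hdr
    )
    log_stage("quantify", sprintf(
      "%d metabolites", length(metabolite_columns(met_table))
    ))
  }, error = function(e) fail("quantify", e))

  # -- stage 6: univariate -------------------------------------------
  tryCatch({
    uni <- univariate_analysis(met_table, config$thresholds)
    differential <- select_differential(uni, config$thresholds)
    write_csv_commented(
      as.data.frame(uni), file.path(outdir, "univariate.csv"), hdr
    )
    write_csv_commented(
      data.frame(
        metabolite = uni$metabolite,
        log2_fold_change = uni$log2_fold_change,
        p_adjusted = uni$p_adjusted
      ),
      file.path(outdir, "fold_change_plot.csv"), hdr
    )
    log_stage("univariate", sprintf("%d differential", length(differential)))
  }, error = function(e) fail("univariate", e))

  # -- stage 7: intersection -----------------------------------------
  tryCatch({
    sig <- significant_metabolites(
      profile, annotation, nrow(scaled$values), config$bin_alpha
    )
    plsda_set <- sig$metabolite[sig$significant]
    cs <- characteristic_intersection(plsda_set, differential)
    jsonlite::write_json(
      list(
        config = hash,
        plsda_significant = cs$plsda_significant,
        univariate_differential = cs$univariate_differential,
        characteristic = cs$characteristic
      ),
      file.path(outdir, "characteristic.json"),
      auto_unbox = TRUE, digits = NA
    )
    log_stage("intersection", sprintf(
      "%d characteristic", length(cs$characteristic)
    ))
  }, error = function(e) fail("intersection", e))

  # -- stage 8: networks ---------------------------------------------
  tryCatch({
    log2fc <- stats::setNames(uni$log2_fold_change, uni$metabolite)
    nets <- lapply(c(marine = "marine", terrestrial = "terrestrial"),
      function(g) {
        net <- build_network(
          correlation_matrix(met_table, g), log2fc,
          config$network_threshold, g
        )
        write_network(
          net,
          file.path(outdir, sprintf("network_%s.graphml", g)),
          file.path(outdir, sprintf("network_%s_edges.csv", g)),
          hdr
        )
        net
      }
    )
    write_csv_commented(
      as.data.frame(nets$marine$nodes),
      file.path(outdir, "network_nodes.csv"), hdr
    )
    diffs <- differential_edges(nets$marine, nets$terrestrial)
    write_csv_commented(
      data.frame(
        set = c(
          rep("marine_only", nrow(diffs$exclusive_a)),
          rep("terrestrial_only", nrow(diffs$exclusive_b)),
          rep("shared", nrow(diffs$shared))
        ),
        from = c(diffs$exclusive_a$from, diffs$exclusive_b$from, diffs$shared$from),
        to = c(diffs$exclusive_a$to, diffs$exclusive_b$to, diffs$shared$to)
      ),
      file.path(outdir, "network_differential_edges.csv"), hdr
    )
    log_stage("network", sprintf(
      "marine %d / terrestrial %d edges",
      nrow(nets$marine$edges), nrow(nets$terrestrial$edges)
    ))
  }, error = function(e) fail("network", e))

  jsonlite::write_json(
    list(
      package = "metabonmr",
      version = as.character(utils::packageVersion("metabonmr")),
      seed = config$seed,
      config_hash = hash,
      stages = stages,
      summary = list(
        n_samples = nrow(binned$values),
        n_bins = ncol(binned$values),
        R2Y = model$R2Y,
        Q2 = perm$observed_Q2,
        permutation_p_Q2 = perm$empirical_p_Q2,
        n_plsda_significant = length(plsda_set),
        n_differential = length(differential),
        n_characteristic = length(cs$characteristic),
        edges_marine = nrow(nets$marine$edges),
        edges_terrestrial = nrow(nets$terrestrial$edges)
      )
    ),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  cat(sprintf(
    "[%7.2fs] manifest written (%d stages)\n",
    as.numeric(Sys.time() - t_all, units = "secs"), length(stages)
  ), file = log_path, append = TRUE)
  invisible(outdir)
}


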