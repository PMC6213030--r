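#' Read an annotation map from CSV
#'
#' Expects columns `metabolite`, `ppm_low`, `ppm_high`; a metabolite may
#' span several rows (several integration windows). Overlapping windows
#' across metabolites are permitted and flagged with a warning.
#'
#' @param path CSV path (lines starting with `#` are skipped).
#' @return An annotation tibble of class `annotation_map`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  ann <- tibble::as_tibble(df[, c("metabolite", "ppm_low", "ppm_high")])
  class(ann) <- c("annotation_map", class(ann))
  ann
}

#' Quantify metabolites by integrating annotated bins
#'
#' For each metabolite, sums the bins whose centers fall inside any of
#' its integration windows of the normalized (unscaled) matrix. Windows
#' shared between metabolites are flagged with a warning; a window
#' covering no kept bin is an error naming the metabolite.
#'
#' @param normalized An `nmr_normalized` (or `nmr_binned`) object.
#' @param annotation Annotation tibble (`metabolite`, `ppm_low`,
#'   `ppm_high`).
#' @return A tibble of class `metabolite_table`: `sample_id`, `group`
#'   (when metadata is attached), then one numeric column per metabolite.
#' @export
quantify_metabolites <- function(normalized, annotation) {
  stopifnot(inherits(normalized, "nmr_binned"))
  centers <- normalized$bin_centers
  mets <- unique(annotation$metabolite)
  bin_sets <- lapply(mets, function(m) {
    win <- annotation[annotation$metabolite == m, , drop = FALSE]
    idx <- unique(unlist(
      purrr::map2(win$ppm_low, win$ppm_high, function(lo, hi) {
        which(centers >= lo & centers <= hi)
      })
    ))
    if (length(idx) == 0) {
      stop(sprintf(
        "no kept bins fall in the integration windows of '%s'", m
      ), call. = FALSE)
    }
    sort(idx)
  })
  names(bin_sets) <- mets
  counts <- table(unlist(bin_sets))
  if (any(counts > 1)) {
    warning(sprintf(
      "%d bin(s) are shared by more than one metabolite's windows",
      sum(counts > 1)
    ))
  }
  vals <- vapply(bin_sets, function(idx) {
    rowSums(normalized$values[, idx, drop = FALSE])
  }, numeric(nrow(normalized$values)))
  out <- tibble::tibble(sample_id = normalized$sample_ids)
  if (!is.null(normalized$metadata) &&
      "group" %in% names(normalized$metadata)) {
    out$group <- normalized$metadata$group
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  class(out) <- c("metabolite_table", class(out))
  out
}
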