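#' Construct a 1D NMR spectrum
#'
#' A spectrum is a two-column tibble (`ppm`, `intensity`) with a `sample_id`
#' attribute. The ppm axis must be strictly monotone and intensities finite.
#' Internally axes are stored ascending; plotting uses the NMR convention
#' (ppm decreasing left to right).
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `ppm`.
#' @param sample_id Character label for the sample.
#' @return A tibble of class `nmr_spectrum` with columns `ppm`, `intensity`.
#' @export
#' @examples
#' sp <- nmr_spectrum(seq(0, 10, by = 0.01), rnorm(1001), "demo")
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("`ppm` axis must be strictly monotone", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (length(d) && all(d < 0)) { # store ascending
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  class(out) <- c("nmr_spectrum", class(out))
  attr(out, "sample_id") <- as.character(sample_id)
  out
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum> %s: %d points, %.3f-%.3f ppm\n",
    sample_id(x), nrow(x), min(x$ppm), max(x$ppm)
  ))
  NextMethod()
}

#' Sample identifier of a spectrum
#' @param x An `nmr_spectrum`.
#' @return Character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read a spectrum from a two-column ASCII file
#'
#' Expects one (ppm, intensity) pair per line, separated by whitespace,
#' tab or comma; lines starting with `#` are comments.
#'
#' @param path File path.
#' @param sample_id Sample label; defaults to the file name without
#'   extension.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  ppm <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
  intensity <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))
  nmr_spectrum(ppm, intensity, sample_id)
}

#' Write a spectrum as two-column ASCII
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.6f\t%.10g", spectrum$ppm, spectrum$intensity), con)
  invisible(path)
}

#' Read a cohort of spectra from a samples-by-ppm CSV matrix
#'
#' The header row holds ppm values; the first column holds sample ids.
#'
#' @param path CSV path. Lines starting with `#` are skipped.
#' @return A named list of [nmr_spectrum()] objects.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1]])
  ppm <- as.numeric(colnames(df)[-1])
  out <- lapply(seq_along(ids), function(i) {
    nmr_spectrum(ppm, as.numeric(df[i, -1]), ids[i])
  })
  stats::setNames(out, ids)
}

#' Write a cohort of spectra as a samples-by-ppm CSV matrix
#'
#' All spectra must share a common ppm axis.
#'
#' @param spectra List of [nmr_spectrum()] objects.
#' @param path Output CSV path.
#' @param header Optional comment line written first (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(spectra, path, header = NULL) {
  axes <- lapply(spectra, function(s) s$ppm)
  if (length(spectra) > 1) {
    same <- vapply(
      axes[-1], function(a) isTRUE(all.equal(a, axes[[1]])), logical(1)
    )
    if (!all(same)) stop("spectra must share a common ppm axis", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(spectra, function(s) s$intensity))
  df <- data.frame(
    sample_id = vapply(spectra, sample_id, character(1)),
    mat, check.names = FALSE
  )
  colnames(df) <- c("sample_id", format_ppm(axes[[1]]))
  write_csv_commented(df, path, header)
  invisible(path)
}

format_ppm <- function(x) sprintf("%.6f", x)

# CSV writer that supports a '#'-prefixed header line; deterministic output.
write_csv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con,
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
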