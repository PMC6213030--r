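#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy PCA scores
#'
#' @param x An `nmr_pca`.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `group` (when known), one column per
#'   component.
#' @method tidy nmr_pca
#' @export
tidy.nmr_pca <- function(x, ...) {
  out <- tibble::tibble(sample_id = rownames(x$scores))
  if (!is.null(x$metadata) && "group" %in% names(x$metadata)) {
    out$group <- x$metadata$group
  }
  dplyr::bind_cols(out, tibble::as_tibble(x$scores))
}

#' One-row PCA summary
#' @param x An `nmr_pca`.
#' @param ... Unused.
#' @return Tibble with per-component explained-variance fractions.
#' @method glance nmr_pca
#' @export
glance.nmr_pca <- function(x, ...) {
  k <- ncol(x$scores)
  ev <- x$explained_variance_fraction[seq_len(k)]
  out <- tibble::as_tibble(as.list(stats::setNames(
    ev, paste0("explained_PC", seq_len(k))
  )))
  out$total_explained <- sum(ev)
  out
}

#' Tidy PLS-DA scores
#' @param x An `nmr_plsda`.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `group`, one column per latent variable.
#' @method tidy nmr_plsda
#' @export
tidy.nmr_plsda <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = rownames(x$scores) %||% seq_len(nrow(x$scores)),
      group = x$groups
    ),
    tibble::as_tibble(x$scores)
  )
}

#' One-row PLS-DA summary
#' @param x An `nmr_plsda`.
#' @param ... Unused.
#' @return Tibble: `n_components`, `R2X`, `R2Y`.
#' @method glance nmr_plsda
#' @export
glance.nmr_plsda <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components, R2X = x$R2X, R2Y = x$R2Y
  )
}

#' Tidy permutation-test draws
#' @param x A `plsda_permutation`.
#' @param ... Unused.
#' @return Tibble: `permutation`, `R2Y`, `Q2`.
#' @method tidy plsda_permutation
#' @export
tidy.plsda_permutation <- function(x, ...) {
  tibble::tibble(
    permutation = seq_len(x$n_permutations),
    R2Y = x$permuted_R2Y,
    Q2 = x$permuted_Q2
  )
}

#' One-row permutation-test summary
#' @param x A `plsda_permutation`.
#' @param ... Unused.
#' @return Tibble: observed R2Y/Q2, empirical p on Q2, n, seed.
#' @method glance plsda_permutation
#' @export
glance.plsda_permutation <- function(x, ...) {
  tibble::tibble(
    observed_R2Y = x$observed_R2Y,
    observed_Q2 = x$observed_Q2,
    empirical_p_Q2 = x$empirical_p_Q2,
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}
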