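#' Threshold configuration for differential selection
#'
#' @param p_threshold Significance threshold on the test p-value
#'   (default 0.05).
#' @param fc_upper,fc_lower Fold-change bounds: a metabolite is
#'   fold-change-relevant when FC > `fc_upper` or FC < `fc_lower`
#'   (defaults 1.5 and 0.67).
#' @param normality_alpha Shapiro-Wilk level gating the test choice
#'   (default 0.05).
#' @param use_adjusted_p Select on Benjamini-Hochberg-adjusted p instead
#'   of raw p (default FALSE: the selection criterion cites the test
#'   p-value; adjusted values are still reported).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(p_threshold = 0.05, fc_upper = 1.5,
                             fc_lower = 0.67, normality_alpha = 0.05,
                             use_adjusted_p = FALSE) {
  if (!(fc_lower > 0 && fc_lower < 1 && fc_upper > 1)) {
    stop("need 0 < fc_lower < 1 < fc_upper", call. = FALSE)
  }
  for (v in c(p_threshold, normality_alpha)) {
    if (v <= 0 || v >= 1) stop("thresholds must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      p_threshold = p_threshold, fc_upper = fc_upper, fc_lower = fc_lower,
      normality_alpha = normality_alpha,
      use_adjusted_p = isTRUE(use_adjusted_p)
    ),
    class = "threshold_config"
  )
}

shapiro_p <- function(x) {
  # Shapiro-Wilk is undefined for constant samples; treat as a normality
  # failure (normality cannot be affirmed)
  if (length(unique(x)) < 3 || stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group test for one metabolite
#'
#' Runs Shapiro-Wilk on each group; when both pass (p >= alpha) a
#' two-sided Welch two-sample t-test is applied, otherwise a two-sided
#' Mann-Whitney U test with tie correction (normal approximation with
#' continuity correction).
#'
#' @param x_marine,y_terrestrial Numeric vectors (each >= 3 values).
#' @param normality_alpha Shapiro-Wilk level (default 0.05).
#' @return One-row tibble: `normality_p_marine`, `normality_p_terrestrial`,
#'   `test_used` ("t-test" or "mann-whitney"), `statistic`, `p_raw`.
#' @export
test_metabolite <- function(x_marine, y_terrestrial, normality_alpha = 0.05) {
  if (length(x_marine) < 3 || length(y_terrestrial) < 3) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  px <- shapiro_p(x_marine)
  py <- shapiro_p(y_terrestrial)
  if (px >= normality_alpha && py >= normality_alpha) {
    ht <- stats::t.test(x_marine, y_terrestrial)
    used <- "t-test"
  } else {
    ht <- stats::wilcox.test(x_marine, y_terrestrial,
      exact = FALSE, correct = TRUE
    )
    used <- "mann-whitney"
  }
  p <- ht$p.value
  if (is.na(p)) p <- 1 # fully tied data: no evidence of a difference
  tibble::tibble(
    normality_p_marine = px, normality_p_terrestrial = py,
    test_used = used,
    statistic = unname(ht$statistic),
    p_raw = min(1, p)
  )
}

#' Fold change of group means (marine relative to terrestrial)
#'
#' @param x_marine,y_terrestrial Numeric vectors of normalized, unscaled
#'   integrals; the terrestrial mean must be positive.
#' @return One-row tibble: `fold_change`, `log2_fold_change`.
#' @export
fold_change <- function(x_marine, y_terrestrial) {
  m_t <- mean(y_terrestrial)
  if (m_t <= 0) {
    stop("terrestrial group mean must be positive", call. = FALSE)
  }
  fc <- mean(x_marine) / m_t
  tibble::tibble(fold_change = fc, log2_fold_change = log2(fc))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same order).
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-metabolite differential testing of a metabolite table
#'
#' Applies [test_metabolite()] and [fold_change()] to every metabolite of
#' a quantified table and adds Benjamini-Hochberg-adjusted p-values.
#'
#' @param table A metabolite table: tibble with `sample_id`, `group`
#'   (marine/terrestrial) and one numeric column per metabolite, or an
#'   object from [quantify_metabolites()].
#' @param config A [threshold_config()] (only `normality_alpha` is used
#'   here).
#' @return A tibble of class `univariate_result`, one row per metabolite:
#'   normality p-values, `test_used`, `statistic`, `p_raw`, `p_adjusted`,
#'   `fold_change`, `log2_fold_change`.
#' @export
univariate_analysis <- function(table, config = threshold_config()) {
  mets <- metabolite_columns(table)
  g <- table$group
  rows <- purrr::map_dfr(mets, function(m) {
    x <- table[[m]][g == "marine"]
    y <- table[[m]][g == "terrestrial"]
    dplyr::bind_cols(
      tibble::tibble(metabolite = m),
      test_metabolite(x, y, config$normality_alpha),
      fold_change(x, y)
    )
  })
  rows$p_adjusted <- bh_adjust(rows$p_raw)
  rows <- rows[, c(
    "metabolite", "normality_p_marine", "normality_p_terrestrial",
    "test_used", "statistic", "p_raw", "p_adjusted",
    "fold_change", "log2_fold_change"
  )]
  class(rows) <- c("univariate_result", class(rows))
  rows
}

metabolite_columns <- function(table) {
  setdiff(names(table), c("sample_id", "strain", "group", "medium"))
}

#' Select differential metabolites
#'
#' A metabolite is differential when its p-value (raw by default,
#' adjusted when `config$use_adjusted_p`) is below `p_threshold` AND its
#' fold change lies outside (`fc_lower`, `fc_upper`).
#'
#' @param result A [univariate_analysis()] result.
#' @param config A [threshold_config()].
#' @return Character vector of selected metabolite names (input order).
#' @export
select_differential <- function(result, config = threshold_config()) {
  p <- if (config$use_adjusted_p) result$p_adjusted else result$p_raw
  hit <- p < config$p_threshold &
    (result$fold_change > config$fc_upper |
      result$fold_change < config$fc_lower)
  result$metabolite[hit]
}
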