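#' Group-specific Pearson correlation matrix of metabolites
#'
#' Pairwise Pearson correlations over the samples of one group only.
#' Constant metabolites have undefined correlations; these are recorded
#' as 0 and flagged. The diagonal is always 1.
#'
#' @param table A metabolite table (tibble with `sample_id`, `group` and
#'   one column per metabolite).
#' @param group Group label to subset on ("marine" or "terrestrial");
#'   needs >= 3 samples.
#' @return A symmetric correlation matrix with attribute `constant`
#'   (logical per metabolite).
#' @export
correlation_matrix <- function(table, group) {
  if (!group %in% table$group) {
    stop(sprintf("group '%s' not present", group), call. = FALSE)
  }
  sub <- table[table$group == group, metabolite_columns(table), drop = FALSE]
  if (nrow(sub) < 3) stop("group needs >= 3 samples", call. = FALSE)
  X <- as.matrix(sub)
  constant <- apply(X, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constant") <- constant
  r
}

#' Build a thresholded inter-metabolite correlation network
#'
#' Connects every unordered metabolite pair with |r| strictly greater
#' than `threshold`. Edge weight is |r|, edge sign records the
#' correlation direction (positive/negative, the warm/cool color coding
#' of the network figures); each node carries the log2 fold change of
#' marine relative to terrestrial as its attribute.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (from
#'   [correlation_matrix()]).
#' @param log2fc Named per-metabolite log2 fold changes (marine vs
#'   terrestrial).
#' @param threshold Strict |r| cutoff in \[0, 1) (default 0.6). Note that
#'   at small sample sizes (e.g. 6 per group) |r| > 0.6 is not
#'   significant at alpha = 0.05; the threshold is descriptive.
#' @param group Optional group label stored on the network.
#' @return A list of class `metab_network`: `nodes` tibble (`metabolite`,
#'   `log2_fold_change`), `edges` tibble (`from`, `to`, `r`, `weight`,
#'   `sign`), `threshold`, `group`.
#' @export
build_network <- function(corr, log2fc = NULL, threshold = 0.6,
                          group = NULL) {
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must be in [0, 1)", call. = FALSE)
  }
  mets <- colnames(corr)
  if (is.null(log2fc)) log2fc <- stats::setNames(rep(NA_real_, length(mets)), mets)
  nodes <- tibble::tibble(
    metabolite = mets,
    log2_fold_change = unname(log2fc[mets])
  )
  pairs <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = mets[pairs[, 1]],
    to = mets[pairs[, 2]],
    r = corr[pairs],
    weight = abs(corr[pairs]),
    sign = ifelse(corr[pairs] >= 0, "positive", "negative")
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold, group = group),
    class = "metab_network"
  )
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf(
    "<metab_network>%s %d nodes, %d edges (|r| > %.2f)\n",
    if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
    nrow(x$nodes), nrow(x$edges), x$threshold
  ))
  invisible(x)
}

#' Intersection of multivariate and univariate hits
#'
#' The characteristic metabolites of a comparison: those both significant
#' in the PLS-DA loading profile and differential by the univariate
#' criteria.
#'
#' @param plsda_set,univariate_set Character vectors of metabolite names
#'   from the same universe.
#' @return A list of class `characteristic_set` with `plsda_significant`,
#'   `univariate_differential` and `characteristic` (sorted
#'   intersection).
#' @export
characteristic_intersection <- function(plsda_set, univariate_set) {
  structure(
    list(
      plsda_significant = plsda_set,
      univariate_differential = univariate_set,
      characteristic = sort(intersect(plsda_set, univariate_set))
    ),
    class = "characteristic_set"
  )
}

#' @export
print.characteristic_set <- function(x, ...) {
  cat(sprintf(
    "<characteristic_set> %d PLS-DA, %d univariate, %d characteristic\n",
    length(x$plsda_significant), length(x$univariate_differential),
    length(x$characteristic)
  ))
  invisible(x)
}

edge_key <- function(edges) {
  paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
}

#' Compare two group-specific correlation networks
#'
#' Returns the edges exclusive to each network and the edges present in
#' both, flagging shared edges whose correlation sign flips between
#' groups (e.g. a metabolite positively correlated with partners in one
#' group but negatively in the other).
#'
#' @param net_a,net_b `metab_network` objects on the same node universe.
#' @return A list with tibbles `exclusive_a`, `exclusive_b`, `shared`
#'   (with columns `r_a`, `r_b`, `sign_flip`).
#' @export
differential_edges <- function(net_a, net_b) {
  if (!setequal(net_a$nodes$metabolite, net_b$nodes$metabolite)) {
    stop("networks must share the same node universe", call. = FALSE)
  }
  ka <- edge_key(net_a$edges)
  kb <- edge_key(net_b$edges)
  shared_keys <- intersect(ka, kb)
  ea <- net_a$edges[match(shared_keys, ka), , drop = FALSE]
  eb <- net_b$edges[match(shared_keys, kb), , drop = FALSE]
  shared <- tibble::tibble(
    from = ea$from, to = ea$to,
    r_a = ea$r, r_b = eb$r,
    sign_flip = sign(ea$r) != sign(eb$r)
  )
  list(
    exclusive_a = net_a$edges[!(ka %in% kb), , drop = FALSE],
    exclusive_b = net_b$edges[!(kb %in% ka), , drop = FALSE],
    shared = shared
  )
}

#' Convert a network to an igraph object
#'
#' @param network A `metab_network`.
#' @return An undirected `igraph` graph with `log2_fold_change` vertex
#'   attribute and `r`, `weight`, `sign` edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "metab_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges),
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' Export a network as GraphML and edge-list CSV
#'
#' @param network A `metab_network`.
#' @param path_graphml GraphML output path (skipped if NULL).
#' @param path_edges Edge-list CSV path (skipped if NULL).
#' @param header Optional comment line for the CSV.
#' @return The network, invisibly.
#' @export
write_network <- function(network, path_graphml = NULL, path_edges = NULL,
                          header = NULL) {
  if (!is.null(path_graphml)) {
    igraph::write_graph(as_igraph(network), path_graphml, format = "graphml")
  }
  if (!is.null(path_edges)) {
    write_csv_commented(as.data.frame(network$edges), path_edges, header)
  }
  invisible(network)
}
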