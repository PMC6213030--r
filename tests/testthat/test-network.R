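toy_table <- function(X, groups) {
  out <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(nrow(X))),
      group = groups
    ),
    tibble::as_tibble(X)
  )
  class(out) <- c("metabolite_table", class(out))
  out
}

test_that("group correlation matrices match the direct Pearson formula", {
  X <- cbind(
    a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1), d = c(5, 1, 4)
  )
  tab <- toy_table(X, rep("marine", 3))
  r <- correlation_matrix(tab, "marine")
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  # direct-formula oracle
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(r[i, j], pearson(X[, i], X[, j]), tolerance = 1e-12)
    }
  }
  # constant metabolite: undefined correlations recorded as 0 and flagged
  Xc <- cbind(X, e = c(2, 2, 2))
  rc <- correlation_matrix(toy_table(Xc, rep("marine", 3)), "marine")
  expect_true(attr(rc, "constant")["e"])
  expect_equal(unname(rc["a", "e"]), 0)
  expect_equal(unname(rc["e", "e"]), 1)
  expect_error(correlation_matrix(tab, "terrestrial"), "not present")
})

test_that("network construction applies the strict |r| threshold", {
  corr <- diag(3)
  dimnames(corr) <- list(c("A", "B", "C"), c("A", "B", "C"))
  corr["A", "B"] <- corr["B", "A"] <- 0.9
  corr["A", "C"] <- corr["C", "A"] <- -0.7
  corr["B", "C"] <- corr["C", "B"] <- 0.1
  net <- build_network(corr, c(A = 1, B = -0.5, C = 0))
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$from == "A" & net$edges$to == "B", ]
  ac <- net$edges[net$edges$from == "A" & net$edges$to == "C", ]
  expect_equal(ab$sign, "positive")
  expect_equal(ac$sign, "negative")
  expect_equal(ac$weight, 0.7)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(net$nodes$log2_fold_change, c(1, -0.5, 0))

  # nothing above threshold: empty edge set, all nodes kept
  weak <- diag(3)
  dimnames(weak) <- dimnames(corr)
  weak[upper.tri(weak)] <- weak[lower.tri(weak)] <- 0.6 # not strict >
  none <- build_network(weak, threshold = 0.6)
  expect_equal(nrow(none$edges), 0)
  expect_equal(nrow(none$nodes), 3)
  # threshold 0: complete graph on 3 nodes
  full <- build_network(corr, threshold = 0)
  expect_equal(nrow(full$edges), 3)
  expect_error(build_network(corr, threshold = 1), "threshold")
  # edge count is non-increasing in the threshold
  counts <- vapply(
    c(0, 0.3, 0.6, 0.8, 0.95),
    function(th) nrow(build_network(corr, threshold = th)$edges),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("characteristic metabolites are the ordered intersection", {
  cs <- characteristic_intersection(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(cs$characteristic, c("B", "C"))
  expect_length(
    characteristic_intersection(c("A"), c("B"))$characteristic, 0
  )
  # constructed 30-set and 34-set overlapping in exactly 27 members
  shared <- sprintf("shared%02d", 1:27)
  set30 <- c(shared, sprintf("plsda%02d", 1:3))
  set34 <- c(shared, sprintf("uni%02d", 1:7))
  cs2 <- characteristic_intersection(set30, set34)
  expect_length(cs2$plsda_significant, 30)
  expect_length(cs2$univariate_differential, 34)
  expect_length(cs2$characteristic, 27)
})

test_that("network comparison finds exclusive edges and sign flips", {
  mk <- function(edges_def) {
    corr <- diag(5)
    nm <- LETTERS[1:5]
    dimnames(corr) <- list(nm, nm)
    for (e in edges_def) {
      corr[e[[1]], e[[2]]] <- corr[e[[2]], e[[1]]] <- e[[3]]
    }
    build_network(corr, stats::setNames(rep(0, 5), nm))
  }
  net_a <- mk(list(
    list("A", "B", 0.9), list("A", "C", 0.8), list("B", "C", 0.7),
    list("C", "D", 0.75), list("D", "E", -0.9)
  ))
  net_b <- mk(list(
    list("A", "B", 0.85), list("B", "C", 0.65), list("D", "E", 0.8)
  ))
  d <- differential_edges(net_a, net_b)
  expect_equal(nrow(d$exclusive_a), 2)
  expect_equal(nrow(d$exclusive_b), 0)
  expect_equal(nrow(d$shared), 3)
  flip <- d$shared[d$shared$sign_flip, ]
  expect_equal(paste(flip$from, flip$to), "D E")
  # identical networks: nothing exclusive, no flips
  same <- differential_edges(net_a, net_a)
  expect_equal(nrow(same$exclusive_a), 0)
  expect_equal(nrow(same$exclusive_b), 0)
  expect_false(any(same$shared$sign_flip))
})

test_that("networks round-trip through igraph and GraphML", {
  corr <- diag(3)
  dimnames(corr) <- list(c("A", "B", "C"), c("A", "B", "C"))
  corr["A", "B"] <- corr["B", "A"] <- 0.9
  net <- build_network(corr, c(A = 1, B = 2, C = 3), group = "marine")
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::V(g)$log2_fold_change, c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".graphml")
  edges <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path, edges)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g2), 1)
  expect_match(readLines(edges, n = 2)[1], "from,to")
})
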