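test_that("is_consistent reproduces the signed truth table", {
  expect_true(is_consistent(2.0, 3.1, 1))    # up-up on activation
  expect_true(is_consistent(-2.0, -3.1, 1))  # down-down on activation
  expect_true(is_consistent(2.0, -3.1, -1))  # up-down on repression
  expect_true(is_consistent(-2.0, 3.1, -1))  # down-up on repression
  expect_false(is_consistent(2.0, -3.1, 1))
  expect_false(is_consistent(-2.0, 3.1, 1))
  expect_false(is_consistent(2.0, 3.1, -1))
  expect_false(is_consistent(-2.0, -3.1, -1))
  expect_false(is_consistent(2.0, 3.1, 0))   # neutral edge never consistent
  expect_false(is_consistent(0, 3.1, 1))     # zero statistic has no direction
})

test_that("leaves follow the out-degree-0 / in-degree>=1 definition", {
  g <- chain_graph(c("a", "b", "c"), c(1, 1))
  expect_identical(leaves(g), "c")
  giso <- pathway_graph(c("a", "b", "x"),
                        data.frame(source = "a", target = "b", r = 1))
  expect_identical(leaves(giso), "b")  # isolated x is not a leaf
  gcyc <- pathway_graph(c("a", "b"),
                        data.frame(source = c("a", "b"), target = c("b", "a"),
                                   r = c(1, 1)))
  expect_length(leaves(gcyc), 0L)
})

test_that("directed_distance counts nodes on shortest directed paths", {
  g <- chain_graph(c("a", "b", "c"), c(1, 0))  # neutral edges traversable
  expect_equal(directed_distance(g, "a", "c"), 3)
  expect_equal(directed_distance(g, "a", "b"), 2)
  expect_equal(directed_distance(g, c("a", "b"), c("b", "c")), 1)  # overlap
  expect_equal(directed_distance(g, "c", "a"), Inf)  # no directed path
  expect_error(directed_distance(g, character(), "a"), "non-empty")
  expect_error(directed_distance(g, "zz", "a"), "not in graph")
})

test_that("maximal consistent subgraphs are the consistent components", {
  g <- chain_graph(c("a", "b", "c"), c(1, 1))
  subs <- maximal_consistent_subgraphs(g, c(a = 1, b = 2, c = 3))
  expect_length(subs, 1L)
  expect_setequal(subs[[1]]$nodes, c("a", "b", "c"))
  expect_equal(nrow(subs[[1]]$edges), 2L)

  expect_length(maximal_consistent_subgraphs(g, c(a = 1, b = -2, c = 3)), 0L)
  expect_error(maximal_consistent_subgraphs(g, c(a = 1, b = 2)),
               "without a t statistic.*c")

  # two disjoint consistent fragments -> two components
  g2 <- pathway_graph(letters[1:4],
                      data.frame(source = c("a", "c"), target = c("b", "d"),
                                 r = c(1L, -1L)))
  subs2 <- maximal_consistent_subgraphs(
    g2, c(a = 1, b = 1, c = 2, d = -2))
  expect_length(subs2, 2L)
  expect_identical(sort(vapply(subs2, function(s) s$nodes[1], character(1))),
                   c("a", "c"))
})

test_that("engine agrees with the brute-force oracle on random graphs", {
  set.seed(321)
  for (i in 1:40) {
    nn <- sample(3:8, 1)
    g <- random_pathway(n_nodes = nn, n_edges = sample(min(12, nn * (nn - 1)), 1),
                        activation_fraction = 0.4, neutral_fraction = 0.2,
                        pathway_id = "rnd")
    t <- stats::setNames(rnorm(length(g$nodes)), g$nodes)
    expect_identical(
      subgraph_signature(maximal_consistent_subgraphs(g, t)),
      subgraph_signature(brute_force_maximal_subgraphs(g, t)),
      info = sprintf("replicate %d", i))
  }
})

test_that("subgraph_score applies the reciprocal leaf-distance weight", {
  sg <- structure(list(nodes = c("a", "b"),
                       edges = data.frame(source = "a", target = "b", r = 1L),
                       d = NA_real_, score = NA_real_),
                  class = "consistent_subgraph")
  z <- c(a = 1, b = 2)
  expect_equal(subgraph_score(sg, z, d = 1), 3)
  expect_equal(subgraph_score(sg, z, d = 3), 1)
  expect_equal(subgraph_score(sg, c(a = 1.5, b = -1.5), d = 2), 0)
  expect_equal(subgraph_score(sg, z, d = Inf), 0)
  expect_warning(s <- subgraph_score(sg, z, d = Inf, leafless = TRUE),
                 "no leaves")
  expect_equal(s, 3)
  expect_error(subgraph_score(sg, c(a = 1), d = 1), "without a z")
})

test_that("weight_function resolves forms and directions", {
  w <- weight_function("reciprocal")
  expect_equal(w(1:4), 1 / (1:4))
  expect_equal(w(Inf), 0)
  we <- weight_function("exponential:0.5")
  expect_equal(we(1), 1)
  expect_equal(we(3), exp(-1))
  expect_equal(we(Inf), 0)
  expect_error(weight_function("exponential:-1"), "positive rate")
  expect_error(weight_function("quadratic"), "unknown weight")
})

test_that("global_statistic sums component scores with their distances", {
  # chain a->b->c->d: consistent cascade a,b at distance 3 from leaf d
  g <- chain_graph(letters[1:4], c(1, 1, 1))
  t <- c(a = 2, b = 3, c = -1, d = 2)  # only a->b consistent
  z <- c(a = 0.5, b = 0.7, c = 0, d = 0)
  ps <- global_statistic(g, t, z)
  expect_length(ps$subgraphs, 1L)
  expect_equal(ps$subgraphs[[1]]$d, 3)
  expect_equal(ps$global_stat, (0.5 + 0.7) / 3)

  # no consistent edge -> zero statistic, empty list
  ps0 <- global_statistic(g, c(a = 1, b = -1, c = 1, d = -1),
                          z, weight = "reciprocal")
  expect_equal(ps0$global_stat, 0)
  expect_length(ps0$subgraphs, 0L)

  # two components sum (possibly with negative parts)
  g2 <- pathway_graph(letters[1:4],
                      data.frame(source = c("a", "c"), target = c("b", "d"),
                                 r = c(1L, 1L)))
  ps2 <- global_statistic(g2, c(a = 1, b = 1, c = 1, d = 1),
                          c(a = 0.8, b = 0.4, c = -0.3, d = -0.1))
  expect_equal(ps2$global_stat, 1.2 - 0.4)
  # deterministic ordering: best score first
  expect_equal(ps2$subgraphs[[1]]$score, 1.2)

  # leafless cycle falls back to w = 1 with a warning
  gcyc <- pathway_graph(c("a", "b"),
                        data.frame(source = c("a", "b"), target = c("b", "a"),
                                   r = c(1L, 1L)))
  expect_warning(pc <- global_statistic(gcyc, c(a = 1, b = 1),
                                        c(a = 0.3, b = 0.4)),
                 "no leaves")
  expect_equal(pc$global_stat, 0.7)
})

test_that("global statistic is invariant to flipping all t signs", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_pathway(8, 10, pathway_id = "flip")
    t <- stats::setNames(rnorm(8), g$nodes)
    z <- stats::setNames(rnorm(8), g$nodes)
    a <- suppressWarnings(global_statistic(g, t, z)$global_stat)
    b <- suppressWarnings(global_statistic(g, -t, z)$global_stat)
    expect_equal(a, b)
  }
})

test_that("fast permutation path equals the reference path", {
  set.seed(55)
  catalog <- lapply(1:5, function(i)
    random_pathway(8, 10, pathway_id = sprintf("fp%d", i)))
  ds <- simulate_expression(catalog, seed = 56)
  u <- gene_universe(ds, catalog)
  gs <- gene_stats(ds, catalog)
  tv <- stats::setNames(gs$t, gs$gene)
  zv <- stats::setNames(gs$z, gs$gene)
  wfun <- weight_function("reciprocal")
  for (g in catalog) {
    cp <- acst:::.compile_pathway(g, u)
    fast <- acst:::.fast_global_stat(cp, tv[u], zv[u], wfun)
    ref <- suppressWarnings(global_statistic(g, tv, zv)$global_stat)
    expect_equal(fast, ref, tolerance = 1e-12)
  }
})
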