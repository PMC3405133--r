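test_that("parse_kgml maps gene entries and GErel subtypes to signed edges", {
  kgml <- make_kgml(
    entries = list(list(genes = "hsa:1", type = "gene"),
                   list(genes = "hsa:2", type = "gene")),
    relations = list(list(from = 1, to = 2, type = "GErel",
                          subtype = "expression")))
  g <- parse_kgml(kgml)
  expect_s3_class(g, "pathway_graph")
  expect_setequal(g$nodes, c("hsa:1", "hsa:2"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$r, 1L)
  expect_identical(g$provenance, "kgml")
  expect_identical(g$pathway_id, "path:test01")

  # multi-gene entry expansion replicates the repression edge to all members
  g2 <- parse_kgml(make_kgml(
    entries = list(list(genes = "hsa:1 hsa:2", type = "gene"),
                   list(genes = "hsa:3", type = "gene")),
    relations = list(list(from = 1, to = 2, type = "GErel",
                          subtype = "repression"))))
  expect_setequal(g2$nodes, c("hsa:1", "hsa:2", "hsa:3"))
  expect_equal(nrow(g2$edges), 2L)
  expect_true(all(g2$edges$r == -1L))
  expect_setequal(g2$edges$source, c("hsa:1", "hsa:2"))
  expect_true(all(g2$edges$target == "hsa:3"))

  # missing subtype -> neutral edge
  g3 <- parse_kgml(make_kgml(
    entries = list(list(genes = "hsa:1", type = "gene"),
                   list(genes = "hsa:2", type = "gene")),
    relations = list(list(from = 1, to = 2, type = "GErel"))))
  expect_equal(g3$edges$r, 0L)
})

test_that("parse_kgml keeps only GErel relations and only gene entries", {
  kgml <- make_kgml(
    entries = list(list(genes = "hsa:1", type = "gene"),
                   list(genes = "hsa:2", type = "gene"),
                   list(genes = "cpd:C00001", type = "compound")),
    relations = list(list(from = 1, to = 2, type = "PPrel",
                          subtype = "phosphorylation"),
                     list(from = 1, to = 3, type = "GErel",
                          subtype = "expression")))
  g <- parse_kgml(kgml)
  # PPrel dropped; GErel to a compound endpoint dropped with it
  expect_setequal(g$nodes, c("hsa:1", "hsa:2"))
  expect_equal(nrow(g$edges), 0L)
})

test_that("parse_kgml error and degenerate branches", {
  expect_error(parse_kgml("<pathway><entry broken"), "KGML parse error")
  expect_warning(
    g <- parse_kgml(make_kgml(
      entries = list(list(genes = "cpd:C1", type = "compound")),
      relations = list())),
    "no gene entries")
  expect_length(g$nodes, 0L)
  # self-loops from group expansion are dropped, duplicates deduplicated
  g2 <- suppressWarnings(parse_kgml(make_kgml(
    entries = list(list(genes = "hsa:1 hsa:2", type = "gene"),
                   list(genes = "hsa:2", type = "gene")),
    relations = list(list(from = 1, to = 2, type = "GErel",
                          subtype = "expression"),
                     list(from = 1, to = 2, type = "GErel",
                          subtype = "expression")))))
  expect_false(any(g2$edges$source == g2$edges$target))
  expect_equal(nrow(g2$edges), 1L)  # hsa:1 -> hsa:2 once
})

test_that("parse_edgelist handles the dialect, errors name line numbers", {
  g <- parse_edgelist("a\tb\t+1\nb\tc\t-1")
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$r), c(-1L, 1L))

  # word tokens, header, comments
  g2 <- parse_edgelist(c("# a comment", "source\ttarget\tsign",
                         "x\ty\tactivation", "y\tz\trepression",
                         "z\tw\tneutral"))
  expect_equal(g2$edges$r[g2$edges$source == "z"], 0L)

  expect_error(parse_edgelist("a\ta\t+1"), "line 1.*self-loop")
  expect_error(parse_edgelist("a\tb\t+1\na\tb\t+1"), "line 2.*duplicate")
  expect_error(parse_edgelist("a\tb\tmaybe"), "line 1.*unknown sign")
  expect_warning(g3 <- parse_edgelist(""), "empty")
  expect_length(g3$nodes, 0L)
})

test_that("edge-list round trip is the identity up to ordering", {
  set.seed(123)
  for (i in 1:10) {
    g <- random_pathway(n_nodes = 8, n_edges = sample(0:14, 1),
                        pathway_id = sprintf("rt%02d", i))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_edgelist(g, path)
    g2 <- read_edgelist(path)
    expect_setequal(g2$nodes, g$nodes)
    expect_identical(g2$pathway_id, g$pathway_id)
    key <- function(e) sort(paste(e$source, e$target, e$r))
    expect_identical(key(g2$edges), key(g$edges))
  }
})

test_that("restrict_to_measured induces without contraction and is idempotent", {
  g <- chain_graph(c("a", "b", "c"), c(1, 1))
  r1 <- suppressMessages(restrict_to_measured(g, c("a", "c")))
  expect_setequal(r1$nodes, c("a", "c"))
  expect_equal(nrow(r1$edges), 0L)  # no edge contraction through b

  expect_identical(restrict_to_measured(g, c("a", "b", "c", "zzz"))$edges,
                   g$edges)
  expect_warning(r3 <- restrict_to_measured(g, "nope"), "no node is measured")
  expect_length(r3$nodes, 0L)

  r2 <- suppressMessages(restrict_to_measured(g, c("a", "b")))
  expect_identical(suppressMessages(restrict_to_measured(r2, c("a", "b"))), r2)
})

test_that("pathway_graph validates its invariants", {
  expect_error(pathway_graph("a", data.frame(source = "a", target = "b", r = 1)),
               "not in node set")
  expect_error(pathway_graph(c("a", "b"),
                             data.frame(source = "a", target = "a", r = 1)),
               "self-loop")
  expect_error(pathway_graph(c("a", "b"),
                             data.frame(source = "a", target = "b", r = 2)),
               "must be -1, 0 or \\+1")
  expect_error(pathway_graph(c("a", "b"),
                             data.frame(source = c("a", "a"),
                                        target = c("b", "b"), r = c(1, 1))),
               "duplicate")
  # parallel edges with different signs are allowed
  g <- pathway_graph(c("a", "b"),
                     data.frame(source = c("a", "a"), target = c("b", "b"),
                                r = c(1, -1)))
  expect_equal(nrow(g$edges), 2L)
})

test_that("read_pathway_dir builds a catalog keyed by pathway_id", {
  dir <- withr::local_tempdir()
  for (i in 1:3)
    write_edgelist(random_pathway(6, 6, seed = i,
                                  pathway_id = sprintf("pw%d", i)),
                   file.path(dir, sprintf("pw%d.tsv", i)))
  cat <- read_pathway_dir(dir)
  expect_named(cat, c("pw1", "pw2", "pw3"))
  expect_true(all(vapply(cat, inherits, logical(1), "pathway_graph")))
  expect_error(read_pathway_dir(file.path(dir, "nope")), "not found")
})
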