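#' Random synthetic pathway graph
#'
#' Simple directed graph without self-loops: `n_edges` ordered node pairs
#' drawn without replacement, each carrying an independent sign, +1 with
#' probability `activation_fraction`, 0 with `neutral_fraction`, -1
#' otherwise. Defaults (10 nodes, 12 edges, 45% activation, 10% neutral)
#' emulate the size and edge mix of the gene-expression-relation skeleton of
#' a typical curated signaling pathway.
#'
#' @param n_nodes number of gene nodes; node ids are `<pathway_id>_g01`, ...
#' @param n_edges number of directed edges; at most `n_nodes * (n_nodes-1)`.
#' @param activation_fraction,neutral_fraction expected fractions of `+1`
#'   and `0` edges; must lie in `[0, 1]` with sum at most 1.
#' @param seed integer seed for reproducibility (`NULL` = current RNG).
#' @param pathway_id identifier of the generated pathway.
#' @return A [pathway_graph()] with `provenance = "synthetic"`.
#' @export
random_pathway <- function(n_nodes = 10, n_edges = 12,
                           activation_fraction = 0.45,
                           neutral_fraction = 0.10,
                           seed = NULL, pathway_id = "synthetic") {
  if (n_edges > n_nodes * (n_nodes - 1))
    stop("infeasible: a simple digraph on ", n_nodes, " nodes has at most ",
         n_nodes * (n_nodes - 1), " edges")
  if (activation_fraction < 0 || neutral_fraction < 0 ||
      activation_fraction + neutral_fraction > 1)
    stop("fractions must be in [0, 1] and sum to at most 1")
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("%s_g%02d", pathway_id, seq_len(n_nodes))
  # all ordered pairs, excluding the diagonal
  pair_id <- sample.int(n_nodes * (n_nodes - 1), n_edges)
  src_i <- (pair_id - 1L) %/% (n_nodes - 1L) + 1L
  off <- (pair_id - 1L) %% (n_nodes - 1L) + 1L
  tgt_i <- ifelse(off >= src_i, off + 1L, off)
  r <- sample(c(1L, 0L, -1L), n_edges, replace = TRUE,
              prob = c(activation_fraction, neutral_fraction,
                       1 - activation_fraction - neutral_fraction))
  pathway_graph(nodes,
                data.frame(source = nodes[src_i], target = nodes[tgt_i],
                           r = r, stringsAsFactors = FALSE),
                pathway_id = pathway_id, name = pathway_id,
                provenance = "synthetic")
}

#' Specification of a planted consistent cascade
#'
#' Describes one transcription-factor cascade planted into a synthetic
#' dataset: an ordered chain of genes inside a pathway, the signs of its
#' edges, and the effect size of the mean shift in the tested group. The
#' planted shifts follow the cumulative edge-sign products, so the cascade
#' is consistent by construction when `effect > 0`.
#'
#' @param pathway_id pathway the cascade lives in.
#' @param cascade_nodes ordered node ids forming a directed chain.
#' @param edge_signs vector in `-1, +1` of length
#'   `length(cascade_nodes) - 1`.
#' @param effect mean shift in the tested group, in units of the noise sd.
#' @param at_leaf whether the chain terminus is (to be made) a pathway leaf.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(pathway_id, cascade_nodes, edge_signs, effect = 2,
                       at_leaf = TRUE) {
  cascade_nodes <- as.character(cascade_nodes)
  if (length(cascade_nodes) < 2L) stop("a cascade needs >= 2 nodes")
  if (length(edge_signs) != length(cascade_nodes) - 1L)
    stop("edge_signs must have length(cascade_nodes) - 1 entries")
  if (!all(edge_signs %in% c(-1L, 1L)))
    stop("edge_signs must be -1 or +1 (a neutral edge cannot be consistent)")
  if (effect < 0) stop("effect must be >= 0")
  structure(list(pathway_id = pathway_id, cascade_nodes = cascade_nodes,
                 edge_signs = as.integer(edge_signs), effect = effect,
                 at_leaf = isTRUE(at_leaf)),
            class = "plant_spec")
}

# internal: direction of the planted shift of gene k along the chain
# (cumulative product of edge signs, sigma_1 = +1)
.plant_shift_signs <- function(spec) {
  cumprod(c(1L, spec$edge_signs))
}

#' Install a cascade's edges into a pathway graph
#'
#' Ensures the chain described by a [plant_spec()] exists in the graph:
#' existing edges between consecutive chain nodes are replaced by the
#' specified signed edge. With `at_leaf = TRUE` all out-edges of the chain
#' terminus are removed, making it a leaf (distance 1 to the leaf set).
#'
#' @param g a [pathway_graph()] containing all `cascade_nodes`.
#' @param spec a [plant_spec()].
#' @return The modified `pathway_graph`.
#' @export
add_cascade <- function(g, spec) {
  stopifnot(inherits(g, "pathway_graph"), inherits(spec, "plant_spec"))
  miss <- setdiff(spec$cascade_nodes, g$nodes)
  if (length(miss))
    stop("cascade node(s) absent from pathway: ", paste(miss, collapse = ", "))
  e <- g$edges
  nn <- length(spec$cascade_nodes)
  for (k in seq_len(nn - 1L)) {
    a <- spec$cascade_nodes[k]; b <- spec$cascade_nodes[k + 1L]
    e <- e[!(e$source == a & e$target == b), , drop = FALSE]
    e <- rbind(e, data.frame(source = a, target = b,
                             r = spec$edge_signs[k],
                             stringsAsFactors = FALSE))
  }
  if (spec$at_leaf) {
    term <- spec$cascade_nodes[nn]
    e <- e[e$source != term, , drop = FALSE]
  }
  pathway_graph(g$nodes, e, pathway_id = g$pathway_id, name = g$name,
                provenance = g$provenance)
}

#' Simulate a two-group expression dataset over a pathway catalog
#'
#' Baseline values are i.i.d. Normal(0, `noise_sd`) for every catalog gene
#' and subject. For each planted cascade, gene `k` of the chain receives a
#' mean shift of `effect * noise_sd * sigma_k` in the tested group, where
#' `sigma_k` is the cumulative product of the chain's edge signs
#' (`sigma_1 = +1`), so the planted expression changes are consistent with
#' the cascade's topology. Genes in no plant have zero shift, making the
#' two groups exchangeable for them.
#'
#' @param catalog list of [pathway_graph()] objects.
#' @param plants list of [plant_spec()] objects (may be empty).
#' @param n_test,n_control group sizes (each >= 2; default 10 + 10, typical
#'   of the profiled case/control cohorts this emulates).
#' @param noise_sd standard deviation of the measurement noise.
#' @param seed integer seed (`NULL` = current RNG).
#' @return An [expression_dataset()] with labels `"test"` / `"control"` and
#'   `test_label = "test"`.
#' @export
simulate_expression <- function(catalog, plants = list(), n_test = 10,
                                n_control = 10, noise_sd = 1, seed = NULL) {
  if (n_test < 2 || n_control < 2) stop("each group needs >= 2 subjects")
  genes <- sort(unique(unlist(lapply(catalog, `[[`, "nodes"),
                              use.names = FALSE)))
  if (!length(genes)) stop("catalog has no genes")
  for (sp in plants) {
    miss <- setdiff(sp$cascade_nodes, genes)
    if (length(miss))
      stop("plant references gene(s) absent from the catalog: ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  ns <- n_test + n_control
  values <- matrix(stats::rnorm(length(genes) * ns, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("s%03d", seq_len(ns))))
  labels <- c(rep("test", n_test), rep("control", n_control))
  test_cols <- seq_len(n_test)
  for (sp in plants) {
    sg <- .plant_shift_signs(sp)
    for (k in seq_along(sp$cascade_nodes)) {
      gene <- sp$cascade_nodes[k]
      values[gene, test_cols] <- values[gene, test_cols] +
        sp$effect * noise_sd * sg[k]
    }
  }
  expression_dataset(values, labels, test_label = "test")
}

#' Brute-force enumeration of maximal consistent subgraphs
#'
#' Independent oracle for [maximal_consistent_subgraphs()], restated from
#' the definition: enumerate every nonempty subset of the consistent edges,
#' keep the weakly-connected ones, and among those the setwise-maximal
#' ones. A connected consistent edge subset is maximal exactly when no
#' consistent edge outside it touches its node set (adding a node-sharing
#' edge preserves weak connectivity; a disjoint edge destroys it), which is
#' what the maximality filter checks after the exhaustive connectivity scan.
#' Guarded to graphs of at most 10 nodes.
#'
#' @param g a [pathway_graph()] with at most 10 nodes.
#' @param t_by_gene named signed t statistics covering `g$nodes`.
#' @return List of `consistent_subgraph` objects, sorted by smallest node
#'   id for comparability.
#' @export
brute_force_maximal_subgraphs <- function(g, t_by_gene) {
  stopifnot(inherits(g, "pathway_graph"))
  if (length(g$nodes) > 10L)
    stop("brute force guarded to <= 10 nodes (exponential enumeration)")
  e <- g$edges
  if (!nrow(e)) return(list())
  ok <- sign(t_by_gene[e$source]) * sign(t_by_gene[e$target]) * e$r == 1
  e <- e[ok, , drop = FALSE]
  nc <- nrow(e)
  if (!nc) return(list())
  s <- match(e$source, g$nodes); t <- match(e$target, g$nodes)
  n <- length(g$nodes)
  # weak connectivity of an edge subset via depth-first search
  connected <- function(idx) {
    if (length(idx) == 1L) return(TRUE)
    vs <- unique(c(s[idx], t[idx]))
    seen <- rep(FALSE, n); seen[vs[1]] <- TRUE
    stack <- vs[1]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      nb <- unique(c(t[idx][s[idx] == v], s[idx][t[idx] == v]))
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    all(seen[vs])
  }
  conn_sets <- list()
  for (mask in seq_len(2^nc - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nc) - 1L)) != 0L)
    if (connected(idx)) conn_sets[[length(conn_sets) + 1L]] <- idx
  }
  maximal <- Filter(function(idx) {
    vs <- unique(c(s[idx], t[idx]))
    outside <- setdiff(seq_len(nc), idx)
    !any(s[outside] %in% vs | t[outside] %in% vs)
  }, conn_sets)
  subs <- lapply(maximal, function(idx) {
    ed <- e[idx, , drop = FALSE]
    rownames(ed) <- NULL
    structure(list(nodes = sort(unique(c(ed$source, ed$target))),
                   edges = ed, d = NA_real_, score = NA_real_),
              class = "consistent_subgraph")
  })
  subs[order(vapply(subs, function(sg) min(sg$nodes), character(1)))]
}
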