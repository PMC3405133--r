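#' Consistency of a signed regulatory relation
#'
#' A directed edge from a transcription factor to a target gene with
#' interaction sign `r` is *consistent* with the observed expression changes
#' when `sign(t_source) * sign(t_target) * r == +1`: both genes move up or
#' both down across an activating edge, or in opposite directions across a
#' repressing edge. Non-standardized signed t statistics are used here —
#' their signs reflect the real direction of change. A zero statistic or a
#' neutral edge (`r = 0`) is never consistent.
#'
#' @param t_source,t_target signed statistics of the edge endpoints
#'   (vectorized).
#' @param r interaction sign(s) in `-1, 0, +1`.
#' @return Logical vector.
#' @export
is_consistent <- function(t_source, t_target, r) {
  sign(t_source) * sign(t_target) * r == 1
}

# internal: in/out degree from an edge data frame, in g$nodes order
.degrees <- function(g) {
  out_d <- table(factor(g$edges$source, levels = g$nodes))
  in_d <- table(factor(g$edges$target, levels = g$nodes))
  list(out = as.integer(out_d), `in` = as.integer(in_d))
}

#' Leaves of a pathway graph
#'
#' A leaf is a node with at least one incoming edge and no outgoing edge:
#' the pathway's terminal effectors, proxies of the induced cellular
#' response. Isolated nodes (degree 0) are not leaves. All edges, including
#' neutral `r = 0` ones, count toward the degrees.
#'
#' @param g a [pathway_graph()].
#' @return Character vector of leaf node ids (possibly empty, e.g. for pure
#'   cycles).
#' @export
leaves <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  d <- .degrees(g)
  g$nodes[d$out == 0L & d$`in` >= 1L]
}

# internal: forward adjacency list over node indices (unique, sign ignored:
# every edge is traversable for distance purposes)
.adjacency <- function(g, reverse = FALSE) {
  n <- length(g$nodes)
  adj <- vector("list", n)
  if (nrow(g$edges)) {
    s <- match(g$edges$source, g$nodes)
    t <- match(g$edges$target, g$nodes)
    if (reverse) { tmp <- s; s <- t; t <- tmp }
    for (k in seq_along(s)) adj[[s[k]]] <- c(adj[[s[k]]], t[k])
    adj <- lapply(adj, unique)
  }
  adj
}

#' Directed distance between node sets
#'
#' The number of nodes in the shortest directed path starting at any node of
#' `from_nodes` and ending at any node of `to_nodes`: 1 if the sets overlap,
#' 2 for a direct edge, and so on; `Inf` when no directed path exists. All
#' edges of `g`, including neutral ones, are traversable.
#'
#' @param g a [pathway_graph()].
#' @param from_nodes,to_nodes character vectors of node ids (subsets of
#'   `g$nodes`); `from_nodes` must be non-empty.
#' @return Positive integer-valued numeric, or `Inf`.
#' @export
directed_distance <- function(g, from_nodes, to_nodes) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!length(from_nodes)) stop("from_nodes must be non-empty")
  bad <- setdiff(c(from_nodes, to_nodes), g$nodes)
  if (length(bad)) stop("node(s) not in graph: ", paste(bad, collapse = ", "))
  if (!length(to_nodes)) return(Inf)
  if (length(intersect(from_nodes, to_nodes))) return(1)
  adj <- .adjacency(g)
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  frontier <- match(unique(from_nodes), g$nodes)
  dist[frontier] <- 1
  to_idx <- match(unique(to_nodes), g$nodes)
  level <- 1
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   which(is.finite(dist)))
    if (!length(nxt)) break
    level <- level + 1
    dist[nxt] <- level
    if (any(nxt %in% to_idx)) return(level)
    frontier <- nxt
  }
  Inf
}

# internal: node-count distance from each node to the leaf set, via
# multi-source BFS on the reversed graph. Leaves themselves are at 1.
.dist_to_leaves <- function(g) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  lv <- match(leaves(g), g$nodes)
  if (!length(lv)) return(dist)
  radj <- .adjacency(g, reverse = TRUE)
  dist[lv] <- 1
  frontier <- lv
  level <- 1
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(radj[frontier], use.names = FALSE)),
                   which(is.finite(dist)))
    if (!length(nxt)) break
    level <- level + 1
    dist[nxt] <- level
    frontier <- nxt
  }
  dist
}

#' Position weight functions
#'
#' Resolve a weight specification into the function `w(d)` that converts a
#' subgraph's directed distance to the leaf set into a multiplicative
#' weight. `"reciprocal"` (the default) is `w(d) = 1/d` — weight 1 at the
#' pathway end, decaying upstream — and `"exponential:LAMBDA"` is
#' `w(d) = exp(-LAMBDA * (d - 1))`. Both give `w(Inf) = 0`: a subgraph with
#' no directed route to any terminal effector may not induce a cellular
#' response and scores 0.
#'
#' @param weight `"reciprocal"`, or `"exponential:<lambda>"` with a positive
#'   rate, or an arbitrary function of `d`.
#' @return A vectorized function `w(d)`.
#' @export
weight_function <- function(weight = "reciprocal") {
  if (is.function(weight)) return(weight)
  if (identical(weight, "reciprocal"))
    return(function(d) ifelse(is.finite(d), 1 / d, 0))
  if (grepl("^exponential:", weight)) {
    lambda <- as.numeric(sub("^exponential:", "", weight))
    if (!is.finite(lambda) || lambda <= 0)
      stop("exponential weight needs a positive rate, e.g. 'exponential:0.5'")
    return(function(d) ifelse(is.finite(d), exp(-lambda * (d - 1)), 0))
  }
  stop("unknown weight specification: ", weight)
}

# internal: union-find components of the consistent edge set.
# cons_s, cons_t: local node indices of consistent edges.
# Returns integer component id per node index (0 = not in any component).
.edge_components <- function(n, cons_s, cons_t) {
  parent <- seq_len(n)
  for (k in seq_along(cons_s)) {
    a <- cons_s[k]; while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- cons_t[k]; while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[a] <- b
  }
  comp <- integer(n)
  inv <- unique(c(cons_s, cons_t))
  for (v in inv) {
    a <- v; while (parent[a] != a) a <- parent[a]
    comp[v] <- a
  }
  comp
}

#' Maximal consistent subgraphs of a pathway
#'
#' Extracts the inclusion-maximal subgraphs all of whose edges are
#' consistent with the observed direction of expression changes. These are
#' exactly the weakly-connected components of the consistent-edge subgraph:
#' each returned subgraph carries every consistent edge among its nodes and
#' cannot be extended by any node or edge of `g` while remaining consistent.
#' An isolated node is never a result — a consistent relation needs an edge.
#'
#' @param g a [pathway_graph()]; every node must have a t value.
#' @param t_by_gene named numeric vector of signed (non-standardized) t
#'   statistics covering `g$nodes`.
#' @return List of `consistent_subgraph` objects (fields `nodes`, `edges`,
#'   `d`, `score`; the latter two `NA` until scored by
#'   [global_statistic()]). Empty list when no edge is consistent.
#' @export
maximal_consistent_subgraphs <- function(g, t_by_gene) {
  stopifnot(inherits(g, "pathway_graph"))
  miss <- g$nodes[!g$nodes %in% names(t_by_gene)]
  if (length(miss))
    stop("node(s) without a t statistic: ", paste(miss, collapse = ", "))
  e <- g$edges
  if (!nrow(e)) return(list())
  ok <- is_consistent(t_by_gene[e$source], t_by_gene[e$target], e$r)
  if (!any(ok)) return(list())
  e <- e[ok, , drop = FALSE]
  s <- match(e$source, g$nodes); t <- match(e$target, g$nodes)
  comp <- .edge_components(length(g$nodes), s, t)
  lapply(sort(unique(comp[comp > 0L])), function(cid) {
    members <- which(comp == cid)
    keep <- comp[s] == cid
    structure(list(nodes = g$nodes[members],
                   edges = {
                     ed <- e[keep, , drop = FALSE]
                     rownames(ed) <- NULL
                     ed
                   },
                   d = NA_real_, score = NA_real_),
              class = "consistent_subgraph")
  })
}

#' @export
print.consistent_subgraph <- function(x, ...) {
  cat(sprintf("consistent_subgraph: %d nodes, %d edges, d = %s, score = %s\n",
              length(x$nodes), nrow(x$edges),
              format(x$d), format(x$score)))
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Score of one consistent subgraph
#'
#' `gamma(C) = w(d) * sum of z over the member genes`, where `d` is the
#' directed distance from the subgraph to the leaf set of the searched
#' graph and `w` the position weight ([weight_function()]). Cascades ending
#' at the pathway's terminal effectors (`d = 1`) get full weight; upstream
#' ones are down-weighted; unreachable ones (`d = Inf`) score 0. When the
#' graph has no leaves at all (pure cycles) the fallback `w = 1` is applied
#' with a warning so cyclic pathways are not silently zeroed.
#'
#' @param subgraph a `consistent_subgraph`.
#' @param z_by_gene named numeric vector of standardized local statistics.
#' @param d directed distance of the subgraph to the leaves, as computed by
#'   `directed_distance(g, subgraph$nodes, leaves(g))`.
#' @param weight weight specification, see [weight_function()].
#' @param leafless set `TRUE` when `leaves(g)` is empty to apply the
#'   fallback weight 1.
#' @return The numeric score `gamma(C)`.
#' @export
subgraph_score <- function(subgraph, z_by_gene, d, weight = "reciprocal",
                           leafless = FALSE) {
  miss <- subgraph$nodes[!subgraph$nodes %in% names(z_by_gene)]
  if (length(miss))
    stop("node(s) without a z statistic: ", paste(miss, collapse = ", "))
  zsum <- sum(z_by_gene[subgraph$nodes])
  if (leafless) {
    warning("graph has no leaves; using fallback weight w = 1")
    return(zsum)
  }
  weight_function(weight)(d) * zsum
}

#' Global pathway statistic
#'
#' Enumerates the maximal consistent subgraphs of `g`, assigns each its
#' directed distance to the leaf set and its score, and sums the scores into
#' the pathway's global statistic (0 when no consistent subgraph exists).
#' Consistency uses the signed `t_by_gene`; scoring uses the standardized
#' `z_by_gene`. Subgraphs are returned sorted by decreasing score, ties by
#' smallest node id, for deterministic output.
#'
#' @param g a [pathway_graph()] restricted to measured genes.
#' @param t_by_gene named signed t statistics covering `g$nodes`.
#' @param z_by_gene named standardized local statistics covering `g$nodes`.
#' @param weight weight specification, see [weight_function()].
#' @return An object of class `pathway_score`: list with `pathway_id`,
#'   `name`, `global_stat`, `subgraphs`.
#' @export
global_statistic <- function(g, t_by_gene, z_by_gene, weight = "reciprocal") {
  subs <- maximal_consistent_subgraphs(g, t_by_gene)
  leafless <- length(leaves(g)) == 0L
  dist <- .dist_to_leaves(g)
  if (length(subs)) {
    if (leafless)
      warning(sprintf("pathway %s has no leaves; using fallback weight w = 1",
                      g$pathway_id))
    wfun <- weight_function(weight)
    subs <- lapply(subs, function(sg) {
      sg$d <- min(dist[match(sg$nodes, g$nodes)])
      zsum <- sum(z_by_gene[sg$nodes])
      sg$score <- if (leafless) zsum else wfun(sg$d) * zsum
      sg
    })
    ord <- order(-vapply(subs, `[[`, numeric(1), "score"),
                 vapply(subs, function(sg) min(sg$nodes), character(1)))
    subs <- subs[ord]
  }
  structure(list(pathway_id = g$pathway_id, name = g$name,
                 global_stat = sum(vapply(subs, `[[`, numeric(1), "score")),
                 subgraphs = subs),
            class = "pathway_score")
}

#' @export
print.pathway_score <- function(x, ...) {
  cat(sprintf("pathway_score %s: global = %.4f, %d consistent subgraph(s)\n",
              x$pathway_id, x$global_stat, length(x$subgraphs)))
  invisible(x)
}

# ---- fast permutation path -------------------------------------------------
# The permutation null recomputes the global statistic ~ B x |pathways| times.
# Graph topology is label-invariant, so everything that does not depend on t
# (node indices into the universe, per-node distance to leaves, leaflessness)
# is compiled once per pathway.

.compile_pathway <- function(g, universe) {
  gidx <- match(g$nodes, universe)
  if (anyNA(gidx))
    stop("pathway ", g$pathway_id, " has nodes outside the universe; ",
         "call restrict_to_measured() first")
  ls <- match(g$edges$source, g$nodes)
  lt <- match(g$edges$target, g$nodes)
  list(pathway_id = g$pathway_id, n_local = length(g$nodes), gidx = gidx,
       usrc = gidx[ls], utgt = gidx[lt], lsrc = ls, ltgt = lt,
       r = as.integer(g$edges$r), dist = .dist_to_leaves(g),
       leafless = length(leaves(g)) == 0L)
}

# t, z: universe-indexed numeric vectors; wfun: weight function.
.fast_global_stat <- function(cp, t, z, wfun) {
  if (!length(cp$r)) return(0)
  s <- sign(t)
  ok <- s[cp$usrc] * s[cp$utgt] * cp$r == 1
  if (!any(ok)) return(0)
  comp <- .edge_components(cp$n_local, cp$lsrc[ok], cp$ltgt[ok])
  inv <- which(comp > 0L)
  zsum <- numeric(cp$n_local)
  dmin <- rep(Inf, cp$n_local)
  for (v in inv) {
    cid <- comp[v]
    zsum[cid] <- zsum[cid] + z[cp$gidx[v]]
    if (cp$dist[v] < dmin[cid]) dmin[cid] <- cp$dist[v]
  }
  total <- 0
  for (cid in unique(comp[inv])) {
    w <- if (cp$leafless) 1 else wfun(dmin[cid])
    total <- total + w * zsum[cid]
  }
  total
}
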