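#' Signed directed pathway graph
#'
#' Construct a `pathway_graph`, the in-memory representation of one signaling
#' pathway: a directed graph whose nodes are gene identifiers and whose edges
#' carry an interaction sign `r` with `r = +1` for activation (the source
#' transcription factor increases expression of the target), `r = -1` for
#' repression, and `r = 0` for a relation of unknown or neutral direction.
#' Neutral edges can never be part of a consistent subgraph but they do
#' contribute to topology (leaves, directed distances), so they are kept.
#'
#' @param nodes character vector of gene identifiers (opaque strings).
#' @param edges data frame with columns `source`, `target` (gene ids) and
#'   `r` (integer in `-1, 0, +1`). Zero-row data frames are allowed.
#' @param pathway_id short stable identifier of the pathway.
#' @param name human-readable pathway name.
#' @param provenance one of `"kgml"`, `"edgelist"`, `"synthetic"`.
#' @return An object of class `pathway_graph`: a list with elements `nodes`
#'   (sorted character vector), `edges` (data frame `source`, `target`, `r`),
#'   `pathway_id`, `name`, `provenance`.
#' @examples
#' g <- pathway_graph(c("a", "b"), data.frame(source = "a", target = "b", r = 1L))
#' leaves(g)
#' @export
pathway_graph <- function(nodes, edges = NULL, pathway_id = "pathway",
                          name = pathway_id,
                          provenance = c("edgelist", "kgml", "synthetic")) {
  provenance <- match.arg(provenance)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) nodes <- unique(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        r = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        r = as.integer(edges$r), stringsAsFactors = FALSE)
  }
  g <- structure(list(nodes = sort(nodes), edges = edges,
                      pathway_id = as.character(pathway_id),
                      name = as.character(name), provenance = provenance),
                 class = "pathway_graph")
  validate_pathway_graph(g)
}

#' Validate pathway graph invariants
#'
#' Checks that every edge endpoint is a node, that there are no self-loops,
#' no duplicated `(source, target, r)` triples, and that all signs lie in
#' `-1, 0, +1`. Parallel edges differing in `r` are permitted.
#'
#' @param g a `pathway_graph`.
#' @return `g`, invisibly unchanged, or an error.
#' @export
validate_pathway_graph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  e <- g$edges
  if (nrow(e)) {
    bad <- setdiff(unique(c(e$source, e$target)), g$nodes)
    if (length(bad))
      stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "))
    if (any(e$source == e$target))
      stop("self-loop edge(s) present: ",
           paste(unique(e$source[e$source == e$target]), collapse = ", "))
    if (!all(e$r %in% c(-1L, 0L, 1L)))
      stop("edge sign r must be -1, 0 or +1")
    key <- paste(e$source, e$target, e$r, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (source, target, r) edge triple(s)")
  }
  invisible(g)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d nodes, %d edges [%s]\n",
              x$pathway_id, x$name, length(x$nodes), nrow(x$edges),
              x$provenance))
  invisible(x)
}

#' @export
format.pathway_graph <- function(x, ...) {
  sprintf("<pathway_graph %s: %d nodes, %d edges>",
          x$pathway_id, length(x$nodes), nrow(x$edges))
}

# internal: deduplicate edge triples, drop self-loops
.clean_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  key <- paste(edges$source, edges$target, edges$r, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a pathway graph in the signed edge-list dialect
#'
#' The dialect is a UTF-8 TSV with header `source	target	sign` and sign
#' tokens `+1`, `-1`, `0`. Isolated nodes (no incident edges) are preserved
#' as comment lines `# node: <id>` so that reading the file back restores the
#' full node set.
#'
#' @param g a `pathway_graph`.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @seealso [parse_edgelist()]
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pathway_id: %s", g$pathway_id), con)
  writeLines(sprintf("# name: %s", g$name), con)
  iso <- setdiff(g$nodes, unique(c(g$edges$source, g$edges$target)))
  for (n in iso) writeLines(sprintf("# node: %s", n), con)
  writeLines("source\ttarget\tsign", con)
  if (nrow(g$edges)) {
    sign_tok <- c(`-1` = "-1", `0` = "0", `1` = "+1")[as.character(g$edges$r)]
    writeLines(paste(g$edges$source, g$edges$target, sign_tok, sep = "\t"), con)
  }
  invisible(path)
}
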