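# Fixture builders shared across test files; everything is generated in code.

# minimal KGML document from a compact description
make_kgml <- function(entries, relations, pathway_name = "path:test01",
                      title = "test pathway") {
  entry_xml <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    sprintf('<entry id="%d" name="%s" type="%s"/>',
            i, paste(e$genes, collapse = " "), e$type)
  }, character(1))
  rel_xml <- vapply(relations, function(r) {
    subs <- if (is.null(r$subtype)) "" else
      sprintf('<subtype name="%s" value="x"/>', r$subtype)
    sprintf('<relation entry1="%d" entry2="%d" type="%s">%s</relation>',
            r$from, r$to, r$type, subs)
  }, character(1))
  paste0('<?xml version="1.0"?>\n',
         sprintf('<pathway name="%s" org="hsa" number="1" title="%s">\n',
                 pathway_name, title),
         paste(entry_xml, collapse = "\n"), "\n",
         paste(rel_xml, collapse = "\n"), "\n</pathway>")
}

# directed chain a -> b -> c ... with given edge signs
chain_graph <- function(nodes, signs, pathway_id = "chain") {
  n <- length(nodes)
  pathway_graph(nodes,
                data.frame(source = nodes[-n], target = nodes[-1],
                           r = as.integer(signs), stringsAsFactors = FALSE),
                pathway_id = pathway_id)
}

# small deterministic two-group dataset
toy_dataset <- function(genes = c("a", "b", "c"), n1 = 2, n2 = 2, seed = 42) {
  set.seed(seed)
  ns <- n1 + n2
  values <- matrix(rnorm(length(genes) * ns), nrow = length(genes),
                   dimnames = list(genes, sprintf("s%d", seq_len(ns))))
  expression_dataset(values, c(rep("case", n1), rep("ctrl", n2)),
                     test_label = "case")
}

# canonical comparison form of a subgraph list (node sets + sorted edge keys)
subgraph_signature <- function(subs) {
  sig <- lapply(subs, function(sg)
    list(nodes = sort(sg$nodes),
         edges = sort(paste(sg$edges$source, sg$edges$target, sg$edges$r))))
  sig[order(vapply(sig, function(s) s$nodes[1], character(1)),
            vapply(sig, function(s) paste(s$edges, collapse = ";"),
                   character(1)))]
}
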