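#' Parse a KGML (KEGG Markup Language) pathway document
#'
#' Reads a KGML XML document and returns the gene-level signed graph that the
#' consistency analysis operates on. Only `entry` elements of type `"gene"`
#' are used; entries listing several gene ids are expanded into one node per
#' gene, with incident edges replicated to every member. Only relations of
#' type `"GErel"` (gene-expression relations: a transcription factor directly
#' regulating a target gene) are kept; a subtype named `"expression"` maps to
#' `r = +1`, `"repression"` to `r = -1`, and any other or missing subtype to
#' `r = 0`. All other relation classes (`PPrel`, `ECrel`, `maplink`, ...) are
#' discarded. Self-loops arising from group expansion are dropped and
#' duplicate edge triples are deduplicated.
#'
#' @param x KGML document: a file path or a single string of XML text.
#' @param pathway_id identifier to use if the document carries none; defaults
#'   to the `name` attribute of the `<pathway>` element, else `"kgml"`.
#' @return A [pathway_graph()] with `provenance = "kgml"`.
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:demo" title="demo">',
#'   '<entry id="1" name="hsa:10" type="gene"/>',
#'   '<entry id="2" name="hsa:20" type="gene"/>',
#'   '<relation entry1="1" entry2="2" type="GErel">',
#'   '<subtype name="expression" value="--&gt;"/></relation></pathway>')
#' parse_kgml(kgml)
#' @export
parse_kgml <- function(x, pathway_id = NULL) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("KGML parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) root <- xml2::xml_root(doc)
  pid <- pathway_id
  if (is.null(pid)) pid <- xml2::xml_attr(root, "name")
  if (is.null(pid) || is.na(pid)) pid <- "kgml"
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  if (!length(entries)) {
    warning("KGML document contains no gene entries; returning empty graph")
    return(pathway_graph(character(), NULL, pathway_id = pid, name = pname,
                         provenance = "kgml"))
  }
  # entry id -> character vector of member gene ids
  genes_of <- lapply(entries, function(e)
    strsplit(trimws(xml2::xml_attr(e, "name")), "\\s+")[[1]])
  names(genes_of) <- xml2::xml_attr(entries, "id")
  nodes <- unique(unlist(genes_of, use.names = FALSE))

  rels <- xml2::xml_find_all(doc, ".//relation[@type='GErel']")
  edges <- data.frame(source = character(), target = character(),
                      r = integer(), stringsAsFactors = FALSE)
  if (length(rels)) {
    parts <- lapply(rels, function(rel) {
      src <- genes_of[[xml2::xml_attr(rel, "entry1")]]
      tgt <- genes_of[[xml2::xml_attr(rel, "entry2")]]
      if (is.null(src) || is.null(tgt)) return(NULL)  # non-gene endpoint
      subs <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
      r <- if ("expression" %in% subs) 1L
           else if ("repression" %in% subs) -1L else 0L
      expand.grid(source = src, target = tgt, r = r,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) edges <- do.call(rbind, parts)
  }
  pathway_graph(nodes, .clean_edges(edges), pathway_id = pid, name = pname,
                provenance = "kgml")
}

.SIGN_TOKENS <- c("+1" = 1L, "1" = 1L, "activation" = 1L,
                  "-1" = -1L, "−1" = -1L, "repression" = -1L,
                  "0" = 0L, "neutral" = 0L)

#' Parse the plain signed edge-list dialect
#'
#' Tab-separated lines `source<TAB>target<TAB>sign` with sign tokens
#' `+1/-1/0` or `activation/repression/neutral`. Lines starting with `#` are
#' comments; a `# node: <id>` comment declares an isolated node; an optional
#' header line `source target sign` is skipped. Nodes are created implicitly
#' from edge endpoints.
#'
#' @param text edge-list content as a single string or character vector of
#'   lines.
#' @param pathway_id,name identifiers for the resulting graph; `# pathway_id:`
#'   and `# name:` comment lines in the file take precedence.
#' @return A [pathway_graph()] with `provenance = "edgelist"`.
#' @export
parse_edgelist <- function(text, pathway_id = "edgelist", name = pathway_id) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  iso <- character()
  src <- character(); tgt <- character(); r <- integer()
  seen <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#", "", ln))
      if (startsWith(body, "pathway_id:"))
        pathway_id <- trimws(sub("^pathway_id:", "", body))
      else if (startsWith(body, "name:"))
        name <- trimws(sub("^name:", "", body))
      else if (startsWith(body, "node:"))
        iso <- c(iso, trimws(sub("^node:", "", body)))
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                   i, length(f)))
    if (identical(tolower(f), c("source", "target", "sign"))) next
    if (!f[3] %in% names(.SIGN_TOKENS))
      stop(sprintf("line %d: unknown sign token '%s'", i, f[3]))
    if (f[1] == f[2])
      stop(sprintf("line %d: self-loop edge '%s'", i, f[1]))
    key <- paste(f[1], f[2], .SIGN_TOKENS[[f[3]]], sep = "\r")
    if (key %in% seen)
      stop(sprintf("line %d: duplicate edge triple %s -> %s (%s)",
                   i, f[1], f[2], f[3]))
    seen <- c(seen, key)
    src <- c(src, f[1]); tgt <- c(tgt, f[2])
    r <- c(r, .SIGN_TOKENS[[f[3]]])
  }
  nodes <- unique(c(src, tgt, iso))
  if (!length(nodes))
    warning("empty edge list; returning empty graph")
  pathway_graph(nodes,
                data.frame(source = src, target = tgt, r = r,
                           stringsAsFactors = FALSE),
                pathway_id = pathway_id, name = name,
                provenance = "edgelist")
}

#' Read one edge-list file
#'
#' @param path path to an edge-list file; the file stem is used as
#'   `pathway_id` unless the file declares one.
#' @return A [pathway_graph()].
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  stem <- sub("\\.[^.]*$", "", basename(path))
  parse_edgelist(readLines(path, encoding = "UTF-8"), pathway_id = stem)
}

#' Read a directory of pathway definition files
#'
#' One pathway per file; `pathway_id` defaults to the file stem (KGML
#' documents carrying their own name keep it).
#'
#' @param dir directory of pathway files.
#' @param format `"edgelist"` (files `*.tsv`/`*.txt`/`*.edges`) or `"kgml"`
#'   (files `*.xml`/`*.kgml`).
#' @return A named list of [pathway_graph()] objects (a pathway catalog).
#' @export
read_pathway_dir <- function(dir, format = c("edgelist", "kgml")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) stop("pathway directory not found: ", dir)
  pat <- if (format == "kgml") "\\.(xml|kgml)$" else "\\.(tsv|txt|edges)$"
  files <- sort(list.files(dir, pattern = pat, full.names = TRUE))
  if (!length(files)) stop("no pathway files matching ", pat, " in ", dir)
  catalog <- lapply(files, function(f) {
    if (format == "kgml") {
      g <- parse_kgml(f)
      if (g$pathway_id == "kgml")
        g$pathway_id <- sub("\\.[^.]*$", "", basename(f))
      g
    } else read_edgelist(f)
  })
  names(catalog) <- vapply(catalog, `[[`, character(1), "pathway_id")
  catalog
}

#' Restrict a pathway graph to a set of measured genes
#'
#' Returns the induced subgraph on `nodes(g)` intersected with `universe`.
#' Edges incident to a removed node are dropped; removal is not transitive
#' (no edge contraction through removed nodes), so a cascade interrupted by
#' an unmeasured gene is genuinely broken.
#'
#' @param g a [pathway_graph()].
#' @param universe character vector of measured gene ids.
#' @return The induced `pathway_graph`; idempotent.
#' @export
restrict_to_measured <- function(g, universe) {
  stopifnot(inherits(g, "pathway_graph"))
  keep <- intersect(g$nodes, universe)
  dropped <- length(g$nodes) - length(keep)
  if (!length(keep))
    warning(sprintf("pathway %s: no node is measured; returning empty graph",
                    g$pathway_id))
  else if (dropped > 0L)
    message(sprintf("pathway %s: dropped %d unmeasured node(s)",
                    g$pathway_id, dropped))
  e <- g$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  pathway_graph(keep, e, pathway_id = g$pathway_id, name = g$name,
                provenance = g$provenance)
}
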