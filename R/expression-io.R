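#' Two-group expression dataset
#'
#' Bundle a gene-by-subject expression matrix with a two-group class label
#' vector. The subject is the permutation unit of the significance test, so
#' labels are attached to columns and validated here once. The Welch t
#' statistic downstream is scale-free, so values may be on any scale
#' (log-intensities, protein abundances, ...).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   subjects in columns (colnames = subject ids). No missing values after
#'   the missing policy is applied.
#' @param labels vector of group labels, one per column of `values`, with
#'   exactly two distinct values; may be named by subject id (order is then
#'   reconciled against `colnames(values)`).
#' @param test_label which label denotes the tested (e.g. disease) group;
#'   `t > 0` downstream means higher expression in this group.
#' @param missing policy for genes with missing values: `"drop"` removes the
#'   gene with a message, `"strict"` errors.
#' @return An object of class `expression_dataset`: list with `values`,
#'   `genes`, `subjects`, `labels` (character vector aligned to columns),
#'   `test_label`.
#' @export
expression_dataset <- function(values, labels, test_label,
                               missing = c("drop", "strict")) {
  missing <- match.arg(missing)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and subject colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate subject ids")
  if (!is.numeric(values)) stop("non-numeric expression values")
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(values), names(labels))
    if (length(miss))
      stop("subject(s) missing from labels: ", paste(miss, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("labels length (", length(labels),
         ") does not match number of subjects (", ncol(values), ")")
  }
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("labels must have exactly two distinct values, found ", length(lv))
  if (!test_label %in% lv)
    stop("test_label '", test_label, "' not among labels: ",
         paste(lv, collapse = ", "))
  if (anyNA(values)) {
    bad <- rowSums(is.na(values)) > 0
    if (missing == "strict")
      stop("missing values in gene(s): ",
           paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
    message(sprintf("dropped %d gene(s) with missing values", sum(bad)))
    values <- values[!bad, , drop = FALSE]
  }
  if (min(table(labels)) < 2L)
    stop("each group needs >= 2 subjects (Welch t needs a variance per group)")
  structure(list(values = values, genes = rownames(values),
                 subjects = colnames(values), labels = labels,
                 test_label = as.character(test_label)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d genes x %d subjects (%s)\n",
              length(x$genes), length(x$subjects),
              paste(sprintf("%s=%d%s", names(tab), tab,
                            ifelse(names(tab) == x$test_label, "*", "")),
                    collapse = ", ")))
  cat("  (* = tested group)\n")
  invisible(x)
}

#' Load expression matrix and labels from TSV files
#'
#' The matrix file is TSV with a header row of subject ids and gene ids in
#' the first column; the labels file is a two-column TSV `subject<TAB>group`
#' (no header, or a `subject group` header which is skipped). Both accept
#' `.gz` compressed variants.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the labels TSV.
#' @param test_label label of the tested group.
#' @param missing missing-value policy, see [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
load_expression <- function(matrix_path, labels_path, test_label,
                            missing = c("drop", "strict")) {
  for (p in c(matrix_path, labels_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  # read.delim handles .gz transparently via file()
  mat <- utils::read.delim(matrix_path, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(mat)
  if (!is.numeric(values)) {
    bad <- colnames(mat)[!vapply(mat, is.numeric, logical(1))]
    stop("non-numeric expression values in column(s): ",
         paste(bad, collapse = ", "))
  }
  lab <- utils::read.delim(labels_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file must have two columns")
  if (identical(tolower(as.character(lab[1, 1:2])), c("subject", "group")))
    lab <- lab[-1, , drop = FALSE]
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  expression_dataset(values, labels, test_label, missing = missing)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [load_expression()]: writes the matrix (gene id column `gene`)
#' and a headerless `subject<TAB>group` labels file.
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,labels_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene = dataset$genes, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(dataset$subjects, dataset$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, labels_path))
}
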