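#' Welch two-sample t statistic
#'
#' Signed t statistic with the Welch (unequal variance) modification:
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with sample
#' (n-1) variances. The standard error is floored at `1e-12` so a gene that
#' is constant in both groups with equal means returns `t = 0` rather than
#' `NaN`. The statistic is used only as a score (no degrees of freedom, no
#' parametric p-value); its sign encodes the direction of change: positive
#' means higher in `x` (the tested group, by the package convention).
#'
#' @param x numeric values of the tested group (length >= 2).
#' @param y numeric values of the control group (length >= 2).
#' @return A single signed numeric value.
#' @examples
#' welch_t(c(2, 4), c(1, 3))  # 0.7071
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t needs >= 2 values per group")
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  (mean(x) - mean(y)) / max(se, 1e-12)
}

# internal: row-wise Welch t for a column split of X (Xsq = X*X precomputed).
# Algebraically identical to welch_t per row; used by the permutation engine
# where ~B*|genes| evaluations are needed.
.welch_rows <- function(X, Xsq, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- (rowSums(Xsq[, i1, drop = FALSE]) - n1 * m1 * m1) / (n1 - 1)
  v2 <- (rowSums(Xsq[, i2, drop = FALSE]) - n2 * m2 * m2) / (n2 - 1)
  # guard tiny negative variances from cancellation
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  se <- sqrt(v1 / n1 + v2 / n2)
  se[se < 1e-12] <- 1e-12
  (m1 - m2) / se
}

#' Gene universe of a pathway catalog
#'
#' The standardization of squared t statistics runs over all genes appearing
#' in any analyzed pathway that are measured in the dataset (not over the
#' whole array). This returns that universe in deterministic (lexicographic)
#' order.
#'
#' @param dataset an [expression_dataset()].
#' @param catalog list of [pathway_graph()] objects.
#' @return Sorted character vector of gene ids.
#' @export
gene_universe <- function(dataset, catalog) {
  stopifnot(inherits(dataset, "expression_dataset"))
  pw_genes <- unique(unlist(lapply(catalog, `[[`, "nodes"), use.names = FALSE))
  u <- sort(intersect(pw_genes, dataset$genes))
  if (!length(u))
    stop(structure(class = c("acst_no_overlap", "error", "condition"),
                   list(message = "no pathway gene measured in the dataset",
                        call = sys.call(-1))))
  u
}

#' Standardize squared t statistics into local statistics
#'
#' Centers and scales the squared t statistics across the gene universe:
#' `z_g = (t_g^2 - mean(t^2)) / sd(t^2)` with the sample (n-1) standard
#' deviation. Standardization makes pathway scores comparable between the
#' observed labeling and the permutation model, which systematically yields
#' smaller t statistics; it is recomputed inside every permutation. If all
#' squared statistics are equal the universe is degenerate: all z are set to
#' 0 with a warning.
#'
#' @param tsq named numeric vector of squared t statistics (>= 2 genes).
#' @return Named numeric vector `z`, same order as `tsq`; `mean(z) = 0`,
#'   `sd(z) = 1` unless degenerate.
#' @export
standardize <- function(tsq) {
  if (length(tsq) < 2L) stop("standardize needs >= 2 genes")
  s <- stats::sd(tsq)
  if (s == 0) {
    warning("degenerate universe: all squared t statistics equal; z set to 0")
    return(tsq * 0)
  }
  (tsq - mean(tsq)) / s
}

# internal: standardize without the degenerate warning (permutation loop)
.standardize_quiet <- function(tsq) {
  s <- stats::sd(tsq)
  if (s == 0) return(tsq * 0)
  (tsq - mean(tsq)) / s
}

#' Per-gene statistics over the pathway gene universe
#'
#' Convenience wrapper computing, for every universe gene, the signed Welch
#' t (tested minus control), its square, and the standardized local
#' statistic z.
#'
#' @param dataset an [expression_dataset()].
#' @param catalog list of [pathway_graph()] objects.
#' @return data frame with columns `gene`, `t`, `tsq`, `z`, one row per
#'   universe gene in lexicographic order.
#' @export
gene_stats <- function(dataset, catalog) {
  u <- gene_universe(dataset, catalog)
  X <- dataset$values[u, , drop = FALSE]
  i1 <- which(dataset$labels == dataset$test_label)
  i2 <- which(dataset$labels != dataset$test_label)
  t <- .welch_rows(X, X * X, i1, i2)
  tsq <- t * t
  data.frame(gene = u, t = t, tsq = tsq, z = standardize(tsq),
             row.names = NULL, stringsAsFactors = FALSE)
}
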