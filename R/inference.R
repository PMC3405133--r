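#' Random permutation of class labels
#'
#' Draws one uniformly random relabeling of the subjects that preserves the
#' two group sizes (the permissible permutations of the subject-sampling
#' null). Permutations are sampled independently with replacement from the
#' permissible set; repeats across draws are possible.
#'
#' @param labels character vector of two-group labels.
#' @return A character vector of the same length and group sizes, randomly
#'   reassigned; uses the current RNG state.
#' @export
permute_labels <- function(labels) {
  labels[sample.int(length(labels))]
}

#' Permutation null distribution of the global statistics
#'
#' For each of `B` class-label permutations the full statistic pipeline is
#' recomputed from scratch: signed Welch t per universe gene, squaring,
#' re-standardization *within that permutation*, and every pathway's global
#' statistic. The observed vector is computed once from the true labels with
#' the same code path, so observed and null values are directly comparable.
#' Shuffling subjects (not genes) preserves the gene-gene correlation
#' structure under the null.
#'
#' @param dataset an [expression_dataset()].
#' @param catalog list of [pathway_graph()] objects; pathways are restricted
#'   to the measured universe internally.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; the whole run is reproducible from it (all `B`
#'   permutations are drawn up front, so results do not depend on pathway
#'   iteration order).
#' @param weight position weight specification, see [weight_function()].
#' @return Object of class `permutation_null`: list with `pathway_ids`,
#'   `observed` (length m), `stats` (m x B matrix), `B`, `seed`, `universe`,
#'   and `observed_scores` (the per-pathway [global_statistic()] objects for
#'   the true labels, with subgraph detail).
#' @export
permutation_null <- function(dataset, catalog, B = 1000, seed = NULL,
                             weight = "reciprocal") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (B < 1) stop("B must be >= 1")
  universe <- gene_universe(dataset, catalog)
  restricted <- lapply(catalog, function(g)
    suppressMessages(suppressWarnings(restrict_to_measured(g, universe))))
  wfun <- weight_function(weight)
  cps <- lapply(restricted, .compile_pathway, universe = universe)
  for (cp in cps)
    if (cp$leafless && any(cp$r != 0L))
      warning(sprintf("pathway %s has no leaves; fallback weight w = 1",
                      cp$pathway_id))

  X <- dataset$values[universe, , drop = FALSE]
  Xsq <- X * X
  i_test <- which(dataset$labels == dataset$test_label)
  i_ctrl <- which(dataset$labels != dataset$test_label)
  n1 <- length(i_test); ns <- ncol(X)

  if (!is.null(seed)) set.seed(seed)
  perm_test <- matrix(0L, n1, B)
  for (b in seq_len(B)) perm_test[, b] <- sample.int(ns, n1)

  score_split <- function(i1, i2) {
    tv <- .welch_rows(X, Xsq, i1, i2)
    zv <- .standardize_quiet(tv * tv)
    vapply(cps, .fast_global_stat, numeric(1), t = tv, z = zv, wfun = wfun)
  }
  observed <- score_split(i_test, i_ctrl)
  m <- length(cps)
  stats <- matrix(0, m, B)
  all_idx <- seq_len(ns)
  for (b in seq_len(B)) {
    i1 <- perm_test[, b]
    stats[, b] <- score_split(i1, all_idx[-i1])
  }
  # observed run once more through the reference path for subgraph detail
  gs <- gene_stats(dataset, catalog)
  tv <- stats::setNames(gs$t, gs$gene)
  zv <- stats::setNames(gs$z, gs$gene)
  observed_scores <- lapply(restricted, function(g)
    suppressWarnings(global_statistic(g, tv, zv, weight = weight)))
  ids <- vapply(restricted, `[[`, character(1), "pathway_id")
  rownames(stats) <- ids
  structure(list(pathway_ids = ids,
                 observed = stats::setNames(observed, ids),
                 stats = stats, B = B, seed = seed, universe = universe,
                 weight = weight, observed_scores = observed_scores),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d pathway(s), B = %d, seed = %s\n",
              length(x$pathway_ids), x$B,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' `p = (1 + #\{b : null_b >= observed\}) / (B + 1)` — the bias-avoiding
#' convention that counts the observed labeling as one member of the
#' permutation sample, so p is never 0 and its minimum is `1/(B+1)`.
#'
#' @param observed observed global statistic.
#' @param null_row numeric vector of B permuted statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_row) {
  (1 + sum(null_row >= observed)) / (length(null_row) + 1)
}

#' Resampling-based FDR point estimate
#'
#' For each observed statistic used as a threshold `c`, the number of
#' observed exceedances is `R(c) = #\{j : observed_j >= c\}` and the
#' permutation-expected number of false exceedances is
#' `Vhat(c) = (1/B) * sum_b #\{j : stats[j, b] >= c\}`. The raw estimate
#' `Vhat/R` is capped at 1 and monotonized step-up style (running minimum
#' over thresholds ordered by increasing statistic), so the adjusted value
#' is non-increasing in the observed statistic; tied thresholds share one
#' value. This is an FDR point estimate for multiple dependent tests, not a
#' p-value adjustment.
#'
#' @param observed numeric vector of m observed statistics.
#' @param stats m x B matrix of permuted statistics.
#' @return Numeric vector of adjusted values in `[0, 1]`, aligned with
#'   `observed`.
#' @export
fdr_point_estimate <- function(observed, stats) {
  stats <- as.matrix(stats)
  m <- length(observed)
  stopifnot(m >= 1, nrow(stats) == m, ncol(stats) >= 1)
  B <- ncol(stats)
  u <- sort(unique(observed))
  all_null <- as.vector(stats)
  raw_u <- vapply(u, function(cc) {
    R <- sum(observed >= cc)
    V <- sum(all_null >= cc) / B
    min(1, V / R)
  }, numeric(1))
  adj_u <- cummin(raw_u)  # running min over increasing thresholds
  adj_u[match(observed, u)]
}

#' Repeatability of two result rankings
#'
#' Spearman rank correlation between two matched vectors of nominal
#' p-values (average ranks for ties), with significance assessed by the
#' F statistic `rho^2 * (n - 2) / (1 - rho^2)` on `(1, n - 2)` degrees of
#' freedom. `|rho| = 1` returns the `Inf` sentinel with p-value 0.
#'
#' @param pvals_a,pvals_b numeric vectors of equal length `n >= 3`, matched
#'   by pathway.
#' @return List with `rho`, `F`, `pvalue`, `n`.
#' @export
repeatability <- function(pvals_a, pvals_b) {
  n <- length(pvals_a)
  if (length(pvals_b) != n) stop("vectors must have equal length")
  if (n < 3) stop("need n >= 3 matched values")
  if (stats::sd(pvals_a) == 0 || stats::sd(pvals_b) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(pvals_a, pvals_b, method = "spearman")
  # floating-point rank correlations can land within an ulp of +/-1
  if (1 - rho^2 <= 1e-12) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- rho^2 * (n - 2) / (1 - rho^2)
    p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  }
  list(rho = rho, F = Fstat, pvalue = p, n = n)
}

#' Bonferroni correction helper
#'
#' @param pvals numeric vector of p-values.
#' @param m number of comparisons (defaults to `length(pvals)`).
#' @return `pmin(1, pvals * m)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, pvals * m)
}

#' Run the full consistent-signal-transduction analysis
#'
#' Ties the pipeline together: gene universe, observed statistics,
#' permutation null, empirical p-values and FDR point estimates, one row per
#' pathway. Pathways with fewer than two measured genes are skipped with a
#' message.
#'
#' @param dataset an [expression_dataset()].
#' @param catalog list of [pathway_graph()] objects.
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param weight position weight, see [weight_function()].
#' @param alpha significance threshold on the adjusted value (default 0.25).
#' @return data frame of class `acst_result` with columns `pathway_id`,
#'   `name`, `n_genes_measured`, `n_subgraphs`, `global_stat`, `pvalue`,
#'   `adj_pvalue`, `significant`, `top_subgraph_nodes`; the
#'   `permutation_null` object is attached as attribute `"null"`.
#' @examples
#' \donttest{
#' cat <- list(random_pathway(seed = 1))
#' ds <- simulate_expression(cat, seed = 2)
#' acst(ds, cat, B = 99, seed = 3)
#' }
#' @export
acst <- function(dataset, catalog, B = 1000, seed = NULL,
                 weight = "reciprocal", alpha = 0.25) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  universe <- gene_universe(dataset, catalog)
  n_meas <- vapply(catalog, function(g)
    length(intersect(g$nodes, universe)), integer(1))
  skipped <- vapply(catalog, `[[`, character(1), "pathway_id")[n_meas < 2L]
  if (length(skipped))
    message("skipping pathway(s) with < 2 measured genes: ",
            paste(skipped, collapse = ", "))
  catalog <- catalog[n_meas >= 2L]
  if (!length(catalog)) stop("no pathway with >= 2 measured genes")
  pn <- permutation_null(dataset, catalog, B = B, seed = seed, weight = weight)
  pv <- vapply(seq_along(pn$pathway_ids), function(j)
    empirical_pvalue(pn$observed[j], pn$stats[j, ]), numeric(1))
  adj <- fdr_point_estimate(pn$observed, pn$stats)
  top_nodes <- vapply(pn$observed_scores, function(ps) {
    if (!length(ps$subgraphs)) return("")
    paste(ps$subgraphs[[1]]$nodes, collapse = ",")
  }, character(1))
  res <- data.frame(
    pathway_id = pn$pathway_ids,
    name = vapply(catalog, `[[`, character(1), "name"),
    n_genes_measured = n_meas[n_meas >= 2L],
    n_subgraphs = vapply(pn$observed_scores, function(ps)
      length(ps$subgraphs), integer(1)),
    global_stat = pn$observed,
    pvalue = pv,
    adj_pvalue = adj,
    significant = as.integer(adj < alpha),
    top_subgraph_nodes = top_nodes,
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$pvalue, -res$global_stat, res$pathway_id), ]
  rownames(res) <- NULL
  attr(res, "null") <- pn
  class(res) <- c("acst_result", "data.frame")
  res
}
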