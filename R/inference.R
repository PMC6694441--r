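#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control at rate `q`: adjusted p-values via
#' [stats::p.adjust()] (method `"BH"`), with rejection flags
#' `adjusted <= q`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (may be empty).
#' @param q FDR rate (default 0.05).
#' @return List with `adjusted` (monotone BH-adjusted p-values) and
#'   `rejected` (logical flags).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  if (length(pvals) == 0L)
    return(list(adjusted = numeric(0), rejected = logical(0)))
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, rejected = !is.na(adjusted) & adjusted <= q)
}

metric_value <- function(bn, metric) {
  switch(metric,
         cp = clustering_coefficient(bn),
         lp = harmonic_path_length(bn),
         q = modularity_greedy(bn)$q,
         stop("unknown global metric: ", metric, call. = FALSE))
}

nodal_values <- function(bn, metric) {
  switch(metric,
         bc = betweenness_centrality(bn),
         degree = as.numeric(node_degree(bn)),
         stop("unknown nodal metric: ", metric, call. = FALSE))
}

# residualize -> correlate for an index subset of a cohort; the single code
# path shared by the observed analysis and every permutation
subset_network <- function(cohort, idx) {
  vals <- cohort$values[idx, , drop = FALSE]
  s <- cohort$subjects[idx, , drop = FALSE]
  res <- residualize(vals, s$age, s$sex, rowMeans(vals))
  correlation_matrix(res)
}

#' Permutation test of a global network metric across a sparsity grid
#'
#' Compares a global property (clustering, harmonic path length or greedy
#' modularity) of two groups' covariance networks. For each of `n_perm`
#' permutations the pooled subjects are reshuffled into two pseudo-groups of
#' the original sizes and the full pipeline — residualize, correlate, binarize
#' at each grid sparsity, evaluate the metric — is re-run, recording the
#' pseudo-group difference. Two-tailed p-values use the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`. Inference is marginal per
#' sparsity (no correction across the grid). Permutations yielding a
#' zero-variance residual column are redrawn, with the count reported.
#'
#' @param cohort A `tau_cohort` containing both groups.
#' @param group_a,group_b Group labels to compare (difference is A minus B).
#' @param metric One of `"cp"`, `"lp"`, `"q"`.
#' @param grid Sparsity grid in (0, 1]; default 8 to 30 percent in steps of 1.
#' @param n_perm Number of permutations (>= 100; the study convention is
#'   5000).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return A data frame of class `permutation_result` with columns `metric`,
#'   `sparsity`, `observed` (A minus B), `p`, `significant`; the null
#'   difference matrix (n_perm by grid) is attached as attribute `"null"`, the
#'   redraw count as `"redraws"`.
#' @export
permutation_test_global <- function(cohort, group_a, group_b,
                                    metric = c("cp", "lp", "q"),
                                    grid = seq(0.08, 0.30, by = 0.01),
                                    n_perm = 5000L, alpha = 0.05,
                                    seed = NULL) {
  metric <- match.arg(metric)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  if (any(grid <= 0 | grid > 1)) stop("grid must lie in (0, 1]",
                                      call. = FALSE)
  validate_cohort(cohort)
  g <- as.character(cohort$subjects$group)
  idx_a <- which(g == group_a); idx_b <- which(g == group_b)
  if (!length(idx_a) || !length(idx_b))
    stop("both groups must be present in the cohort", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  eval_diff <- function(ia, ib) {
    net_a <- subset_network(cohort, ia)
    net_b <- subset_network(cohort, ib)
    vapply(grid, function(S)
      metric_value(binarize_at_sparsity(net_a, S), metric) -
        metric_value(binarize_at_sparsity(net_b, S), metric), numeric(1))
  }
  observed <- eval_diff(idx_a, idx_b)

  pooled <- c(idx_a, idx_b)
  n_a <- length(idx_a)
  null_mat <- matrix(NA_real_, n_perm, length(grid))
  redraws <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      perm <- sample(pooled)
      d <- tryCatch(eval_diff(perm[seq_len(n_a)], perm[-seq_len(n_a)]),
                    error = function(e) NULL)
      if (!is.null(d)) break
      redraws <- redraws + 1L
    }
    null_mat[b, ] <- d
  }
  p <- vapply(seq_along(grid), function(k)
    (1 + sum(abs(null_mat[, k]) >= abs(observed[k]))) / (n_perm + 1),
    numeric(1))
  out <- data.frame(metric = metric, sparsity = grid, observed = observed,
                    p = p, significant = p <= alpha)
  attr(out, "null") <- null_mat
  attr(out, "redraws") <- redraws
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Nodal permutation test at fixed sparsity with FDR correction
#'
#' Compares a per-region nodal property (betweenness centrality or degree)
#' between two groups at a single sparsity, using group-label permutations of
#' the full pipeline as in [permutation_test_global()]. Two-tailed per-region
#' p-values are Benjamini-Hochberg corrected across the N regions.
#'
#' @param cohort A `tau_cohort` containing both groups.
#' @param group_a,group_b Group labels to compare.
#' @param metric One of `"bc"`, `"degree"`.
#' @param s_fixed Fixed sparsity (default 0.08); both observed group networks
#'   must be fully connected at this sparsity.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level for the FDR flags (default 0.05).
#' @param fdr_q FDR rate (default `alpha`).
#' @param seed Optional RNG seed.
#' @return Data frame with one row per region: observed values per group,
#'   `diff`, `p`, `p_adj`, `significant`.
#' @export
permutation_test_nodal <- function(cohort, group_a, group_b,
                                   metric = c("bc", "degree"),
                                   s_fixed = 0.08, n_perm = 5000L,
                                   alpha = 0.05, fdr_q = alpha,
                                   seed = NULL) {
  metric <- match.arg(metric)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  validate_cohort(cohort)
  g <- as.character(cohort$subjects$group)
  idx_a <- which(g == group_a); idx_b <- which(g == group_b)
  if (!length(idx_a) || !length(idx_b))
    stop("both groups must be present in the cohort", call. = FALSE)
  net_a <- subset_network(cohort, idx_a)
  net_b <- subset_network(cohort, idx_b)
  for (nn in list(net_a, net_b)) {
    if (!is_fully_connected(binarize_at_sparsity(nn, s_fixed)))
      stop("observed network disconnected at sparsity ", s_fixed,
           "; use a larger s_fixed (see min_connected_sparsity)",
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  nodal_diff <- function(na, nb)
    nodal_values(binarize_at_sparsity(na, s_fixed), metric) -
    nodal_values(binarize_at_sparsity(nb, s_fixed), metric)
  observed <- nodal_diff(net_a, net_b)

  pooled <- c(idx_a, idx_b)
  n_a <- length(idx_a)
  N <- ncol(cohort$values)
  exceed <- integer(N)
  redraws <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      perm <- sample(pooled)
      d <- tryCatch({
        pa <- subset_network(cohort, perm[seq_len(n_a)])
        pb <- subset_network(cohort, perm[-seq_len(n_a)])
        nodal_diff(pa, pb)
      }, error = function(e) NULL)
      if (!is.null(d)) break
      redraws <- redraws + 1L
    }
    exceed <- exceed + (abs(d) >= abs(observed))
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- fdr_bh(p, q = fdr_q)
  obs_a <- nodal_values(binarize_at_sparsity(net_a, s_fixed), metric)
  obs_b <- nodal_values(binarize_at_sparsity(net_b, s_fixed), metric)
  out <- data.frame(region = colnames(cohort$values),
                    value_a = as.numeric(obs_a), value_b = as.numeric(obs_b),
                    diff = as.numeric(observed), p = p,
                    p_adj = fdr$adjusted, significant = fdr$rejected,
                    row.names = NULL)
  attr(out, "redraws") <- redraws
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "metric") <- metric
  out
}
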