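#' Residualize regional values for age, sex and whole-brain uptake
#'
#' Fits, independently for every region, a linear regression of the regional
#' values on intercept, age, sex and global (whole-brain mean) uptake, and
#' returns the residuals. A covariate that is constant or collinear with the
#' ones before it is dropped with a warning rather than failing.
#'
#' @param values Numeric n-by-N matrix (subjects by regions), n >= 5.
#' @param age,sex,global_uptake Numeric covariate vectors of length n.
#' @return The n-by-N matrix of residuals (same dimnames as `values`).
#' @export
residualize <- function(values, age, sex, global_uptake) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 5L)
    stop("need at least 5 subjects to fit 4 regression parameters",
         call. = FALSE)
  stopifnot(length(age) == n, length(sex) == n, length(global_uptake) == n)
  X <- cbind(intercept = 1, age = age, sex = sex, global = global_uptake)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning("dropping rank-deficient covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
    qr_x <- qr(X)
  }
  res <- qr.resid(qr_x, values)
  dimnames(res) <- dimnames(values)
  res
}

#' Inter-regional Pearson correlation network of one group
#'
#' Computes the N-by-N matrix of Pearson correlation coefficients between all
#' region pairs across subjects, with unit diagonal.
#'
#' @param residuals Numeric n-by-N matrix (typically from [residualize()]),
#'   n >= 3, no zero-variance column.
#' @param group Optional group label to attach.
#' @return An object of class `group_network` with fields `group`, `R`
#'   (symmetric, unit diagonal, entries in \[-1, 1\]) and `n_subjects`.
#' @export
correlation_matrix <- function(residuals, group = NA_character_) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 3L)
    stop("need at least 3 subjects for a correlation matrix", call. = FALSE)
  sds <- apply(residuals, 2L, stats::sd)
  if (any(sds == 0)) {
    zv <- colnames(residuals)[sds == 0]
    if (is.null(zv)) zv <- which(sds == 0)
    stop("zero-variance region(s): ", paste(zv, collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(residuals)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R[R > 1] <- 1; R[R < -1] <- -1
  structure(list(group = group, R = R, n_subjects = nrow(residuals)),
            class = "group_network")
}

#' Build a group's covariance network from a cohort
#'
#' Convenience wrapper: residualizes the cohort's values for age, sex and
#' whole-brain mean uptake (fitted on these subjects only), then correlates.
#' This same code path is re-run on pseudo-groups inside every permutation.
#'
#' @param cohort A `tau_cohort` holding the subjects of one group.
#' @return A `group_network`.
#' @export
group_network <- function(cohort) {
  validate_cohort(cohort)
  s <- cohort$subjects
  res <- residualize(cohort$values, s$age, s$sex, rowMeans(cohort$values))
  grp <- unique(as.character(s$group))
  correlation_matrix(res, group = if (length(grp) == 1L) grp else
    NA_character_)
}

#' @export
print.group_network <- function(x, ...) {
  cat("<group_network> group=", x$group, ", ", nrow(x$R), " regions, n=",
      x$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

# upper-triangle pairs ranked by (-|R|, i, j); the deterministic edge order
# behind every sparsity threshold
ranked_pairs <- function(R) {
  N <- nrow(R)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  a <- abs(R[ut])
  ord <- order(-a, ut[, 1L], ut[, 2L])
  ut[ord, , drop = FALSE]
}

#' Binarize a correlation network at a target sparsity
#'
#' Keeps the K region pairs with the largest absolute correlation, where
#' `K = round(S * N(N-1)/2)` (half away from zero), so the realized edge
#' density matches the requested sparsity to within one edge. Ties at the K-th
#' edge are broken lexicographically on the (row, column) region indices, so
#' the result is deterministic, and edge sets are nested across increasing S.
#'
#' @param net A `group_network`.
#' @param S Target sparsity, the fraction of the `N(N-1)/2` possible edges,
#'   in (0, 1].
#' @return An object of class `binary_network` with fields `P` (symmetric 0/1
#'   adjacency, zero diagonal), `sparsity` and `K` (edge count).
#' @export
binarize_at_sparsity <- function(net, S) {
  stopifnot(inherits(net, "group_network"))
  if (!(S > 0 && S <= 1)) stop("sparsity must lie in (0, 1]", call. = FALSE)
  R <- net$R
  N <- nrow(R)
  M <- N * (N - 1) / 2
  K <- floor(S * M + 0.5)
  if (K == 0L) warning("sparsity ", S, " yields an empty network",
                       call. = FALSE)
  P <- matrix(0L, N, N, dimnames = dimnames(R))
  if (K > 0L) {
    pairs <- ranked_pairs(R)[seq_len(K), , drop = FALSE]
    P[pairs] <- 1L
    P[pairs[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  structure(list(P = P, sparsity = S, K = as.integer(K)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat("<binary_network> ", nrow(x$P), " nodes, K=", x$K, " edges (S=",
      format(x$sparsity), ")\n", sep = "")
  invisible(x)
}

# breadth-first all-pairs geodesic distances on a 0/1 adjacency matrix;
# Inf marks unreachable pairs
bfs_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  reached <- diag(TRUE, N)
  frontier <- diag(1, N)
  d <- 0
  while (TRUE) {
    d <- d + 1
    nxt <- (frontier %*% A > 0) & !reached
    if (!any(nxt)) break
    D[nxt] <- d
    reached <- reached | nxt
    frontier <- nxt * 1
  }
  D
}

# single connected component containing all nodes?
is_fully_connected <- function(bn) {
  A <- bn$P
  if (nrow(A) == 1L) return(TRUE)
  reached <- logical(nrow(A))
  reached[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nb] <- TRUE
    frontier <- nb
  }
  all(reached)
}

#' Smallest grid sparsity giving a fully connected network
#'
#' Scans sparsities `grid_step, 2*grid_step, ...` up to 1 and returns the
#' first at which the binarized network forms a single connected component
#' over all N regions. This is the criterion used to fix the nodal-analysis
#' sparsity: dense enough to include every region, as sparse as possible to
#' limit false-positive connections.
#'
#' @param net A `group_network`.
#' @param grid_step Positive step of the sparsity grid (default 0.01).
#' @return The smallest connecting grid sparsity.
#' @export
min_connected_sparsity <- function(net, grid_step = 0.01) {
  stopifnot(inherits(net, "group_network"))
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  for (S in seq(grid_step, 1, by = grid_step)) {
    if (is_fully_connected(binarize_at_sparsity(net, S))) return(S)
  }
  # a final check at S = 1 in case the grid missed it
  if (is_fully_connected(binarize_at_sparsity(net, 1))) return(1)
  stop("network is not connected at any sparsity up to 1", call. = FALSE)
}
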