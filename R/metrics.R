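#' Nodal degree
#'
#' Number of edges at each node; degrees sum to twice the edge count.
#' Optionally z-scored across nodes (mean 0, SD 1), a scale sometimes used
#' when degrees are compared across networks of different density.
#'
#' @param net A `binary_network`.
#' @param standardize Return the z-scored degree instead of raw counts?
#' @return Named integer vector of per-node degrees (numeric when
#'   standardized).
#' @export
node_degree <- function(net, standardize = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  deg <- as.integer(rowSums(net$P))
  if (standardize) deg <- (deg - mean(deg)) / stats::sd(deg)
  stats::setNames(deg, rownames(net$P))
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the fraction of a node's neighbor pairs that are
#' themselves connected (triangles through the node divided by
#' `deg*(deg-1)/2`). Nodes of degree < 2 contribute 0 and are kept in the
#' average; an empty network is defined as 0 with a warning.
#'
#' @param net A `binary_network` with at least 3 nodes.
#' @return Clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$P
  N <- nrow(A)
  if (N < 3L) stop("need at least 3 nodes", call. = FALSE)
  if (net$K == 0L) {
    warning("empty network: clustering coefficient defined as 0",
            call. = FALSE)
    return(0)
  }
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2       # triangles through each node
  denom <- deg * (deg - 1) / 2
  local <- ifelse(deg >= 2, tri / pmax(denom, 1e-300), 0)
  mean(local)
}

#' Harmonic mean path length
#'
#' The reciprocal of the mean inverse geodesic distance over ordered node
#' pairs, `Lp = 1 / mean(1/d_ij)`. Disconnected pairs have infinite distance
#' and contribute 0 to the mean, so the measure is finite on fragmented
#' graphs — the reason it replaces the plain characteristic path length here.
#'
#' @param net A `binary_network` with at least 2 nodes and 1 edge.
#' @return Harmonic mean path length (>= 1).
#' @export
harmonic_path_length <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  N <- nrow(net$P)
  if (N < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (net$K == 0L)
    stop("path length undefined on an empty network", call. = FALSE)
  D <- bfs_distances(net$P)
  inv <- 1 / D
  diag(inv) <- 0
  1 / (sum(inv) / (N * (N - 1)))
}

# modularity Q of a given partition: sum_c [e_c/m - (d_c/2m)^2]
modularity_q <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) stop("modularity undefined on an empty network", call. = FALSE)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(A[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Greedy agglomerative modularity
#'
#' Starting from singleton communities, repeatedly merges the connected pair
#' of communities with the largest modularity gain (ties broken by the
#' lexicographically smallest community-index pair), and returns the partition
#' attaining the maximum Q along the merge path together with that Q. Q of a
#' partition is `sum_c [e_c/m - (d_c/2m)^2]` with `m` the edge count, `e_c`
#' the intra-community edges and `d_c` the community degree sum.
#'
#' @param net A `binary_network` with at least one edge.
#' @return List with `membership` (named integer vector, communities numbered
#'   1..k in order of first node) and `q` (the modularity of that partition).
#' @export
modularity_greedy <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$P
  N <- nrow(A)
  if (net$K == 0L) stop("modularity undefined on an empty network",
                        call. = FALSE)
  m <- net$K
  # e[i, j]: edges between communities i and j; a[i]: community degree sum
  e <- A / 1
  a <- rowSums(A)
  alive <- rep(TRUE, N)
  member <- seq_len(N)                 # node -> community id
  best_q <- modularity_q(A, member)
  best_member <- member
  cur_q <- best_q
  repeat {
    ids <- which(alive)
    if (length(ids) < 2L) break
    # candidate merges: connected community pairs only
    sub <- e[ids, ids, drop = FALSE]
    conn <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    if (nrow(conn) == 0L) break
    ci <- ids[conn[, 1L]]; cj <- ids[conn[, 2L]]
    dq <- e[cbind(ci, cj)] / m - 2 * (a[ci] / (2 * m)) * (a[cj] / (2 * m))
    ord <- order(-dq, ci, cj)
    pick <- ord[1L]
    i <- ci[pick]; j <- cj[pick]
    # merge j into i
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    e[i, i] <- e[i, i]                 # self-weight now holds 2*e_ij + ...
    a[i] <- a[i] + a[j]
    alive[j] <- FALSE
    e[j, ] <- 0; e[, j] <- 0
    member[member == j] <- i
    cur_q <- cur_q + dq[pick]
    if (cur_q > best_q + 1e-12) {
      best_q <- cur_q
      best_member <- member
    }
  }
  # canonical labels 1..k by first appearance
  labels <- match(best_member, unique(best_member))
  names(labels) <- rownames(A)
  list(membership = labels, q = unname(best_q))
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered pairs (s, t), both distinct from v,
#' of the fraction of shortest s-t paths passing through v (Brandes
#' accumulation). Unreachable pairs contribute 0. Optionally normalized by
#' `(N-1)(N-2)/2`, the number of pairs a node could intermediate.
#'
#' @param net A `binary_network` with at least 2 nodes.
#' @param normalized Divide by `(N-1)(N-2)/2`? Default `FALSE` (raw counts).
#' @return Named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$P
  N <- nrow(A)
  if (N < 2L) stop("need at least 2 nodes", call. = FALSE)
  nbrs <- lapply(seq_len(N), function(i) which(A[i, ] > 0))
  bc <- numeric(N)
  for (s in seq_len(N)) {
    sigma <- numeric(N); sigma[s] <- 1
    dist <- rep(-1L, N); dist[s] <- 0L
    preds <- vector("list", N)
    stack <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      stack <- c(stack, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(N)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                          # ordered -> unordered pairs
  if (normalized) bc <- bc / ((N - 1) * (N - 2) / 2)
  stats::setNames(bc, rownames(A))
}

#' Global metrics of a binary network
#'
#' @param net A `binary_network`.
#' @return Named list with `cp` (clustering coefficient), `lp` (harmonic mean
#'   path length) and `q` (greedy-agglomerative modularity).
#' @export
global_metrics <- function(net) {
  list(cp = clustering_coefficient(net),
       lp = harmonic_path_length(net),
       q = modularity_greedy(net)$q)
}
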