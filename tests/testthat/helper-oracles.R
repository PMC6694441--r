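# Independent brute-force oracles. These deliberately use different
# algorithms and formulas from the package implementation.

# least squares residuals via the normal equations
oracle_residuals <- function(values, X) {
  beta <- solve(t(X) %*% X, t(X) %*% values)
  values - X %*% beta
}

# textbook Pearson coefficient: covariance over product of SDs
oracle_pearson <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# clustering by explicit enumeration of all node triples
oracle_clustering <- function(A) {
  N <- nrow(A)
  local <- numeric(N)
  for (v in seq_len(N)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (A[nb[i], nb[j]] > 0) tri <- tri + 1
    local[v] <- tri / (k * (k - 1) / 2)
  }
  mean(local)
}

# all-pairs distances by Floyd-Warshall
oracle_fw_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_harmonic_lp <- function(A) {
  D <- oracle_fw_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  N <- nrow(A)
  1 / (sum(inv) / (N * (N - 1)))
}

# enumerate every shortest path between two nodes (lists of node vectors)
enumerate_shortest_paths <- function(A, s, t) {
  D <- oracle_fw_distances(A)
  if (!is.finite(D[s, t])) return(list())
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    nxt <- which(A[v, ] > 0 & D[, t] == D[v, t] - 1)
    do.call(c, lapply(nxt, function(w) extend(c(path, w))))
  }
  extend(s)
}

# betweenness by explicit path enumeration over unordered pairs
oracle_betweenness <- function(A) {
  N <- nrow(A)
  bc <- numeric(N)
  for (s in seq_len(N - 1)) for (t in (s + 1):N) {
    paths <- enumerate_shortest_paths(A, s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(paths)
    }
  }
  bc
}

# modularity of a partition via the pairwise null-model formula
oracle_modularity_q <- function(A, membership) {
  m <- sum(A) / 2
  k <- rowSums(A)
  N <- nrow(A)
  q <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  unname(q / (2 * m))
}

# all set partitions of n elements (restricted growth strings), n small
all_partitions <- function(n) {
  out <- list()
  recurse <- function(s, mx) {
    if (length(s) == n) {
      out[[length(out) + 1]] <<- s
      return(invisible())
    }
    for (v in seq_len(mx + 1)) recurse(c(s, v), max(mx, v))
  }
  recurse(1L, 1L)
  out
}

# maximum modularity by exhaustive search over all partitions
oracle_max_modularity <- function(A) {
  parts <- all_partitions(nrow(A))
  qs <- vapply(parts, function(p) oracle_modularity_q(A, p), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# union-find connectivity
oracle_connected <- function(A) {
  N <- nrow(A)
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(N), find, integer(1))
  length(unique(roots)) == 1
}

# BH step-up evaluated literally: largest k with p_(k) <= k*q/m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(k)) rejected[ord[seq_len(max(k))]] <- TRUE
  rejected
}

# Erdos-Renyi style random binary network wrapped as the package's class
random_binary_network <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
  A <- A + t(A)
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  structure(list(P = A, sparsity = sum(A) / 2 / (n * (n - 1) / 2),
                 K = as.integer(sum(A) / 2)),
            class = "binary_network")
}

# random correlation-like symmetric matrix wrapped as a group_network
random_group_network <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(4 * n * n), 4 * n, n)
  structure(list(group = "test", R = cor(X), n_subjects = 4 * n),
            class = "group_network")
}

# small hand-built cohort over the full atlas
toy_cohort <- function(n_per_group = 8, groups = c("A4-T-", "A4+T+"),
                       seed = 99) {
  set.seed(seed)
  atlas <- aal90_atlas()
  n <- n_per_group * length(groups)
  values <- matrix(rnorm(n * nrow(atlas), mean = 1.2, sd = 0.15), n,
                   dimnames = list(sprintf("T%03d", 1:n), atlas$name))
  subjects <- data.frame(
    id = sprintf("T%03d", 1:n),
    group = rep(groups, each = n_per_group),
    age = rnorm(n, 77, 6), sex = rbinom(n, 1, 0.5),
    diagnosis = sample(c("MCI", "NC"), n, replace = TRUE),
    faq = sample(0:12, n, replace = TRUE),
    mmse = sample(25:30, n, replace = TRUE),
    csf_ttau = ifelse(grepl("T\\+$", rep(groups, each = n_per_group)),
                      rnorm(n, 430, 50), rnorm(n, 240, 30)),
    abeta_status = sample(c("positive", "negative"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  subjects$csf_ttau <- ifelse(grepl("T\\+$", subjects$group),
                              pmax(subjects$csf_ttau, 320),
                              pmin(subjects$csf_ttau, 319))
  tau_cohort(values, subjects, atlas)
}
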