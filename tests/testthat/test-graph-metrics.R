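as_bn <- function(A) {
  dimnames(A) <- list(paste0("n", seq_len(nrow(A))),
                      paste0("n", seq_len(nrow(A))))
  structure(list(P = A, sparsity = sum(A) / 2 / choose(nrow(A), 2),
                 K = as.integer(sum(A) / 2)), class = "binary_network")
}

complete_graph <- function(n) as_bn(matrix(1L, n, n) - diag(1L, n))

test_that("clustering coefficient matches triangle enumeration", {
  expect_equal(clustering_coefficient(complete_graph(5)), 1)

  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1L
  expect_equal(clustering_coefficient(as_bn(star)), 0)

  for (seed in 1:10) {
    bn <- random_binary_network(20, 0.25, seed)
    expect_equal(clustering_coefficient(bn), oracle_clustering(bn$P))
  }

  expect_warning(cc <- clustering_coefficient(as_bn(matrix(0L, 4, 4))),
                 "empty")
  expect_equal(cc, 0)
})

test_that("harmonic path length matches all-pairs oracles, including disconnection", {
  expect_equal(harmonic_path_length(complete_graph(6)), 1)

  # two disjoint edges on 4 nodes: 4 of 12 ordered pairs at distance 1
  two_edges <- matrix(0L, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1L
  two_edges[3, 4] <- two_edges[4, 3] <- 1L
  expect_equal(harmonic_path_length(as_bn(two_edges)), 3)

  for (seed in 1:10) {
    bn <- random_binary_network(15, 0.3, seed + 100)
    if (bn$K == 0) next
    expect_equal(harmonic_path_length(bn), oracle_harmonic_lp(bn$P),
                 tolerance = 1e-12)
  }

  expect_error(harmonic_path_length(as_bn(matrix(0L, 3, 3))), "empty")
})

test_that("greedy modularity finds the planted split and respects the exhaustive bound", {
  expect_equal(modularity_greedy(complete_graph(5))$q, 0)
  expect_equal(length(unique(modularity_greedy(complete_graph(5))$membership)),
               1L)

  # two triangles joined by one bridge edge
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  res <- modularity_greedy(as_bn(A))
  expect_equal(unname(res$membership[1:3]), rep(res$membership[[1]], 3))
  expect_equal(unname(res$membership[4:6]), rep(res$membership[[4]], 3))
  ex <- oracle_max_modularity(A)
  expect_equal(res$q, ex$q, tolerance = 1e-12)

  # two 4-cliques in a ring: greedy stays within the exhaustive maximum
  B <- matrix(0L, 8, 8)
  B[1:4, 1:4] <- 1L; B[5:8, 5:8] <- 1L; diag(B) <- 0L
  B[4, 5] <- B[5, 4] <- 1L; B[8, 1] <- B[1, 8] <- 1L
  resB <- modularity_greedy(as_bn(B))
  exB <- oracle_max_modularity(B)
  expect_lte(resB$q, exB$q + 1e-12)
  expect_gte(length(unique(resB$membership)), 2L)

  # returned q always equals direct evaluation of Q on the partition
  for (seed in 1:10) {
    bn <- random_binary_network(12, 0.3, seed + 200)
    if (bn$K == 0) next
    r <- modularity_greedy(bn)
    expect_equal(r$q, oracle_modularity_q(bn$P, r$membership),
                 tolerance = 1e-12)
    expect_gte(r$q, -0.5)
    expect_lt(r$q, 1)
  }
  expect_error(modularity_greedy(as_bn(matrix(0L, 3, 3))), "empty")
})

test_that("betweenness matches explicit shortest-path enumeration", {
  expect_equal(unname(betweenness_centrality(complete_graph(5))), rep(0, 5))

  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  expect_equal(unname(betweenness_centrality(as_bn(path3))), c(0, 1, 0))

  for (seed in 1:10) {
    bn <- random_binary_network(7, 0.4, seed + 300)
    expect_equal(unname(betweenness_centrality(bn)),
                 oracle_betweenness(bn$P), tolerance = 1e-12)
  }

  # cross-check against an established implementation
  skip_if_not_installed("igraph")
  bn <- random_binary_network(25, 0.15, 999)
  g <- igraph::graph_from_adjacency_matrix(bn$P, mode = "undirected")
  expect_equal(unname(betweenness_centrality(bn)),
               unname(igraph::betweenness(g)), tolerance = 1e-9)
  res <- modularity_greedy(bn)
  fg <- igraph::cluster_fast_greedy(g)
  expect_equal(res$q, igraph::modularity(g, igraph::membership(fg)),
               tolerance = 0.05)
})

test_that("degree sums to twice the edge count and normalization is consistent", {
  expect_equal(unname(node_degree(complete_graph(7))), rep(6L, 7))
  expect_equal(unname(node_degree(as_bn(matrix(0L, 4, 4)))), rep(0L, 4))
  bn <- random_binary_network(20, 0.3, 5)
  expect_equal(sum(node_degree(bn)), 2L * bn$K)
  raw <- betweenness_centrality(bn)
  norm <- betweenness_centrality(bn, normalized = TRUE)
  expect_equal(unname(norm), unname(raw) / (19 * 18 / 2))
})

test_that("metrics are invariant under node permutation and Lp shrinks with density", {
  bn <- random_binary_network(15, 0.3, 77)
  set.seed(1)
  perm <- sample(15)
  bp <- as_bn(bn$P[perm, perm])
  expect_equal(clustering_coefficient(bp), clustering_coefficient(bn))
  expect_equal(harmonic_path_length(bp), harmonic_path_length(bn))
  # the greedy merge path (index tie-breaks) may differ under relabeling,
  # so Q is only approximately label-invariant
  expect_lt(abs(modularity_greedy(bp)$q - modularity_greedy(bn)$q), 0.1)
  expect_equal(sort(unname(betweenness_centrality(bp))),
               sort(unname(betweenness_centrality(bn))), tolerance = 1e-12)

  net <- random_group_network(40, seed = 31)
  grid <- c(0.08, 0.15, 0.25, 0.4)
  lps <- vapply(grid, function(S)
    harmonic_path_length(binarize_at_sparsity(net, S)), numeric(1))
  expect_true(all(diff(lps) <= 1e-12))
})
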