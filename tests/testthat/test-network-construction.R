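test_that("residualization removes exactly the modeled covariates", {
  set.seed(101)
  n <- 12
  age <- rnorm(n, 75, 6); sex <- rbinom(n, 1, 0.5); glob <- rnorm(n)

  # values exactly linear in the covariates leave zero residuals
  vals <- outer(age, c(0.5, -1, 2)) + outer(sex, c(1, 0, 3)) + 5
  res <- residualize(vals, age, sex, glob)
  expect_lt(max(abs(res)), 1e-9)

  # constant covariates reduce to column centering (with a warning)
  vals2 <- matrix(rnorm(n * 4), n)
  expect_warning(res2 <- residualize(vals2, rep(1, n), rep(0, n),
                                     rep(2, n)),
                 "rank-deficient")
  expect_equal(res2, scale(vals2, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-12)

  # random case matches the normal-equations oracle entrywise
  vals3 <- matrix(rnorm(n * 5), n)
  res3 <- residualize(vals3, age, sex, glob)
  X <- cbind(1, age, sex, glob)
  expect_equal(res3, oracle_residuals(vals3, X), ignore_attr = TRUE,
               tolerance = 1e-9)
  # orthogonality to the design
  expect_lt(max(abs(t(X) %*% res3)), 1e-8)

  expect_error(residualize(vals3[1:4, ], age[1:4], sex[1:4], glob[1:4]),
               "at least 5")
})

test_that("correlation matrices satisfy their contract and match the textbook formula", {
  set.seed(7)
  vals <- matrix(rpois(20, 10), 5, 4,
                 dimnames = list(NULL, paste0("r", 1:4)))
  net <- correlation_matrix(vals)
  expect_identical(net$R, t(net$R))
  expect_equal(unname(diag(net$R)), rep(1, 4))
  expect_true(all(net$R >= -1 & net$R <= 1))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(net$R[i, j], oracle_pearson(vals[, i], vals[, j]),
                 tolerance = 1e-12)

  # identical and exactly opposite columns
  v2 <- cbind(a = vals[, 1], b = vals[, 1], c = -vals[, 1] + 7)
  net2 <- correlation_matrix(v2)
  expect_equal(net2$R["a", "b"], 1)
  expect_equal(net2$R["a", "c"], -1)

  # zero-variance column errors naming the region
  v3 <- vals; v3[, 2] <- 3
  expect_error(correlation_matrix(v3), "r2")

  # subject-row permutation invariance
  perm <- sample(5)
  expect_equal(correlation_matrix(vals[perm, ])$R, net$R,
               tolerance = 1e-12)
})

test_that("binarization keeps exactly the top-K absolute correlations", {
  # 5-node matrix with distinct |R|: sort-and-cut oracle
  set.seed(42)
  R <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  vals <- c(0.9, -0.8, 0.7, 0.05, 0.5, -0.4, 0.3, 0.2, 0.1, -0.6)
  R[upper.tri(R)] <- vals
  R <- R + t(R); diag(R) <- 1
  net <- structure(list(group = "x", R = R, n_subjects = 10),
                   class = "group_network")
  bn <- binarize_at_sparsity(net, 0.4)
  expect_equal(bn$K, 4L)   # round(0.4 * 10)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  top4 <- ut[order(-abs(R[ut]))[1:4], ]
  expect_equal(sort(bn$P[top4]), rep(1L, 4))
  expect_equal(sum(bn$P) / 2, 4)

  # saturation and degenerate cases
  expect_equal(binarize_at_sparsity(net, 1)$K, 10L)
  expect_true(all(binarize_at_sparsity(net, 1)$P[upper.tri(R)] == 1))
  expect_warning(empty <- binarize_at_sparsity(net, 0.01), "empty")
  expect_equal(empty$K, 0L)
  expect_error(binarize_at_sparsity(net, 0), "sparsity")
})

test_that("edge sets are nested and invariant to monotone transforms of |R|", {
  net <- random_group_network(30, seed = 13)
  grid <- c(0.05, 0.1, 0.2, 0.4)
  bns <- lapply(grid, function(S) binarize_at_sparsity(net, S))
  for (k in seq_len(length(grid) - 1))
    expect_true(all(bns[[k]]$P <= bns[[k + 1]]$P))

  # strictly monotone transform of |R| preserves the ranking hence the edges
  net2 <- net
  net2$R <- sign(net$R) * abs(net$R)^3
  diag(net2$R) <- 1
  for (S in grid)
    expect_identical(binarize_at_sparsity(net2, S)$P,
                     binarize_at_sparsity(net, S)$P)
})

test_that("minimum connecting sparsity matches a union-find grid scan", {
  # explicit construction: N-1 largest |R| values form a spanning path
  N <- 12
  R <- matrix(0, N, N)
  for (i in seq_len(N - 1)) R[i, i + 1] <- R[i + 1, i] <- 0.9 - 0.01 * i
  fill <- which(upper.tri(R) & R == 0)
  set.seed(2)
  R[fill] <- runif(length(fill), 0, 0.3)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  diag(R) <- 1
  dimnames(R) <- list(paste0("n", 1:N), paste0("n", 1:N))
  net <- structure(list(group = "x", R = R, n_subjects = 10),
                   class = "group_network")
  grid_step <- 0.01
  s_min <- min_connected_sparsity(net, grid_step)
  M <- N * (N - 1) / 2
  k_needed <- N - 1
  expect_equal(s_min,
               seq(grid_step, 1, grid_step)[
                 which(floor(seq(grid_step, 1, grid_step) * M + 0.5) >=
                         k_needed)[1]])

  # random matrices vs a linear scan using the union-find oracle
  for (seed in 1:20) {
    net_r <- random_group_network(15, seed = seed)
    s_min <- min_connected_sparsity(net_r, 0.02)
    scan <- seq(0.02, 1, 0.02)
    oracle <- scan[which(vapply(scan, function(S)
      oracle_connected(binarize_at_sparsity(net_r, S)$P),
      logical(1)))[1]]
    expect_equal(s_min, oracle)
  }
})
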