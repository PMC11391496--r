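test_that("modularity matches trivial closed forms", {
  W <- random_weight_matrix(6, seed = 30)
  expect_equal(modularity_q(W, rep(1, 6)), 0, tolerance = 1e-12)
  cl <- two_cliques()
  expect_equal(modularity_q(cl, rep(c(1, 2), each = 4)), 0.5, tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 3, 3), 1:3), "zero total weight")
  expect_error(modularity_q(-W, rep(1, 6)), "negative")
})

test_that("modularity matches the direct double-sum oracle and igraph", {
  skip_if_not_installed("igraph")
  for (s in 1:6) {
    W <- random_weight_matrix(6, seed = s)
    part <- sample(1:3, 6, replace = TRUE)
    q <- modularity_q(W, part)
    expect_equal(q, modularity_oracle(W, part), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(q, igraph::modularity(g, part, weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("modularity and affinity are invariant to label permutation", {
  W <- random_weight_matrix(8, seed = 31)
  part <- c(1, 1, 2, 2, 3, 3, 3, 1)
  relab <- c(3, 3, 1, 1, 2, 2, 2, 3)
  expect_equal(modularity_q(W, part), modularity_q(W, relab))
})

test_that("louvain recovers planted cliques and is deterministic", {
  cl <- two_cliques()
  p <- louvain(cl, seed = 1)
  expect_equal(p$Q, 0.5, tolerance = 1e-10)
  expect_equal(p$n_communities, 2)
  expect_equal(length(unique(p$membership[1:4])), 1)
  expect_equal(length(unique(p$membership[5:8])), 1)
  expect_false(p$membership[1] == p$membership[5])
  expect_identical(louvain(cl, seed = 7), louvain(cl, seed = 7))
  # Q of the returned partition equals modularity of its membership
  W <- random_weight_matrix(12, seed = 32)
  p2 <- louvain(W, seed = 3)
  expect_equal(p2$Q, modularity_q(W, p2$membership), tolerance = 1e-10)
})

test_that("louvain attains the exhaustive maximum on small graphs", {
  hits <- 0
  trials <- 30
  for (s in seq_len(trials)) {
    n <- 5 + (s %% 3)
    W <- random_weight_matrix(n, seed = 300 + s)
    q_best <- max_modularity_oracle(W)
    q_louvain <- louvain(W, seed = s)$Q
    expect_lte(q_louvain, q_best + 1e-10)
    if (q_louvain >= q_best - 1e-10) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})

test_that("consensus co-assignment has the stated matrix structure", {
  cl <- two_cliques()
  P <- consensus_coassignment(cl, runs = 25, master_seed = 5)
  expect_equal(diag(P), rep(1, 8), ignore_attr = TRUE)
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(P * 25, round(P * 25), tolerance = 1e-9) # multiples of 1/runs
  expect_equal(P[1:4, 1:4], matrix(1, 4, 4), ignore_attr = TRUE)
  expect_equal(P[1:4, 5:8], matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("affinity implements the mean co-assignment formula", {
  P <- diag(3)
  dimnames(P) <- list(c("i", "j1", "j2"), c("i", "j1", "j2"))
  P["i", "j1"] <- P["j1", "i"] <- 0.8
  P["i", "j2"] <- P["j2", "i"] <- 0.4
  a <- affinity(P, "i", c("j1", "j2"))
  expect_equal(a$value, 0.6)
  expect_equal(a$n, 2)
  # region inside X: excluded from its own average
  a2 <- affinity(P, "i", c("i", "j1", "j2"))
  expect_equal(a2$value, 0.6)
  expect_equal(a2$n, 2)
  # all co-assigned
  P1 <- matrix(1, 3, 3, dimnames = dimnames(P))
  expect_equal(affinity(P1, "i", c("j1", "j2"))$value, 1)
  expect_error(affinity(P, "i", "i"), "n_Xi = 0")
  expect_error(affinity(P, "zzz", "j1"), "unknown region")
})

test_that("planted two-block structure yields sharp affinity contrast", {
  set.seed(33)
  n <- 10
  blocks <- rep(c("A", "B"), each = n)
  W <- matrix(0.05, 2 * n, 2 * n)
  W[1:n, 1:n] <- 0.4
  W[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.4
  W <- W + matrix(rnorm(4 * n^2, sd = 0.01), 2 * n)
  W <- nonnegative_weights((W + t(W)) / 2)
  diag(W) <- 0
  dimnames(W) <- list(paste0("r", 1:(2 * n)), paste0("r", 1:(2 * n)))
  P <- consensus_coassignment(W, runs = 50, master_seed = 11)
  own <- vapply(1:(2 * n), function(i) {
    mean(P[i, setdiff(which(blocks == blocks[i]), i)])
  }, numeric(1))
  cross <- vapply(1:(2 * n), function(i) {
    mean(P[i, which(blocks != blocks[i])])
  }, numeric(1))
  expect_true(all(own >= 0.9))
  expect_true(all(cross <= 0.2))
})
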