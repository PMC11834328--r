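# Independent naive evaluation of Q by explicit double loop over node pairs.
naive_q <- function(A, gamma, membership) {
  k <- rowSums(A)
  two_m <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - gamma * k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

test_that("model construction enforces the adjacency contract", {
  A <- two_triangles()
  expect_s3_class(modularity_model(A), "modularity_model")
  bad <- A; bad[1, 2] <- 2
  expect_error(modularity_model(bad), "symmetric")
  bad <- A; bad[1, 1] <- 1
  expect_error(modularity_model(bad), "diagonal")
  bad <- A; bad[1, 2] <- bad[2, 1] <- -1
  expect_error(modularity_model(bad), "nonnegative")
  expect_error(modularity_model(A, gamma = 0), "gamma")
  m0 <- modularity_model(matrix(0, 3, 3))
  expect_error(modularity_q(m0, c(1, 1, 2)), "zero total edge weight")
  expect_error(louvain_run(m0), "zero total edge weight")
})

test_that("Q matches hand values and the naive double-loop oracle", {
  model <- modularity_model(two_triangles())
  expect_equal(modularity_q(model, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(model, rep(1, 6)), 0)

  # singleton partition closed form: -sum(k_i^2) / (2m)^2 at gamma 1
  for (seed in 1:5) {
    A <- random_weighted_graph(8, seed)
    model <- modularity_model(A)
    k <- rowSums(A)
    expect_equal(modularity_q(model, 1:8), -sum(k^2) / sum(A)^2,
                 tolerance = 1e-12)
  }

  # naive oracle on random graphs and partitions, several gammas
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    A <- random_weighted_graph(n, seed = 1000 + rep)
    gamma <- sample(c(0.5, 1, 1.7), 1)
    model <- modularity_model(A, gamma = gamma)
    memb <- sample(1:4, n, replace = TRUE)
    expect_equal(modularity_q(model, memb), naive_q(A, gamma, memb),
                 tolerance = 1e-12)
  }

  # invariance under community relabeling and node reordering
  A <- random_weighted_graph(10, seed = 7)
  model <- modularity_model(A)
  memb <- c(1, 1, 2, 2, 2, 3, 3, 1, 2, 3)
  relab <- c(7, 7, 1, 1, 1, 4, 4, 7, 1, 4)
  expect_equal(modularity_q(model, memb), modularity_q(model, relab))
  ord <- sample(10)
  model2 <- modularity_model(A[ord, ord])
  expect_equal(modularity_q(model2, memb[ord]), modularity_q(model, memb))
})

test_that("Louvain recovers unambiguous optima and reports consistent Q", {
  model <- modularity_model(two_triangles())
  for (seed in c(1, 7, 42)) {
    run <- louvain_run(model, seed = seed)
    expect_equal(run$Q, 0.5)
    expect_equal(length(unique(run$membership)), 2L)
    expect_equal(unname(run$membership[1:3]), rep(run$membership[[1]], 3))
  }

  # complete graph: single community, Q = 0 (verified by brute force)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  model5 <- modularity_model(K5)
  run5 <- louvain_run(model5, seed = 3)
  expect_equal(run5$Q, 0)
  expect_equal(length(unique(run5$membership)), 1L)
  expect_equal(brute_force_optimal(model5)$Q, 0)

  # determinism and Q self-consistency
  r1 <- louvain_run(model, seed = 11)
  r2 <- louvain_run(model, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$Q, modularity_q(model, r1$membership), tolerance = 1e-10)

  # never below the all-in-one partition
  for (seed in 1:20) {
    A <- random_weighted_graph(sample(5:15, 1), seed = 2000 + seed)
    m <- modularity_model(A)
    expect_gte(louvain_run(m, seed = seed)$Q,
               modularity_q(m, rep(1, nrow(A))) - 1e-12)
  }
})

test_that("brute force enumerates set partitions and finds the optimum", {
  model <- modularity_model(two_triangles())
  bf <- brute_force_optimal(model)
  expect_equal(bf$Q, 0.5)
  expect_equal(unname(bf$membership), c(1, 1, 1, 2, 2, 2))

  # single edge: both partitions give {0, -0.5}; optimum is one community
  e <- matrix(c(0, 1, 1, 0), 2, 2)
  bfe <- brute_force_optimal(modularity_model(e))
  expect_equal(bfe$Q, 0)
  expect_equal(unname(bfe$membership), c(1, 1))

  expect_error(brute_force_optimal(modularity_model(matrix(0, 2, 2))),
               "zero total edge weight")
  A <- random_weighted_graph(11, seed = 1)
  expect_error(brute_force_optimal(modularity_model(A)), "limited to")
})

test_that("higher resolution never coarsens the brute-force optimum", {
  for (seed in 1:4) {
    A <- random_weighted_graph(6, seed = 3000 + seed)
    counts <- vapply(c(0.5, 1, 2, 4), function(g) {
      bf <- brute_force_optimal(modularity_model(A, gamma = g))
      length(unique(bf$membership))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("Q convention agrees with igraph's weighted modularity", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    A <- random_weighted_graph(12, seed = 4000 + seed)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(
      modularity_q(modularity_model(A), memb),
      igraph::modularity(g, memb, weights = igraph::E(g)$weight),
      tolerance = 1e-12)
  }
})
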