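test_that("modularity closed forms hold", {
  A <- two_triangles()
  # single community at gamma = 1 scores exactly zero
  expect_lt(abs(modularity_score(A, rep(1, 6), 1)), 1e-12)
  # the clique partition of two disconnected triangles scores 1/2
  expect_equal(modularity_score(A, c(1, 1, 1, 2, 2, 2), 1), 0.5)
  expect_error(modularity_score(matrix(0, 3, 3), 1:3), "no edges")
})

test_that("Q is affine and strictly decreasing in gamma for a fixed partition", {
  set.seed(2)
  A <- random_weighted_graph(9)
  p <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  gs <- seq(0.5, 3, by = 0.5)
  qs <- vapply(gs, function(g) modularity_score(A, p, g), numeric(1))
  expect_true(all(diff(qs) < 0))
  # affine: second differences vanish
  expect_lt(max(abs(diff(diff(qs)))), 1e-12)
})

test_that("modularity agrees with igraph's implementation", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:5) {
    A <- random_weighted_graph(12)
    g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                             weighted = TRUE)
    p <- sample(1:3, 12, replace = TRUE)
    for (gam in c(0.7, 1, 1.8))
      expect_equal(modularity_score(A, p, gam),
                   igraph::modularity(g, p, weights = igraph::E(g)$weight,
                                      resolution = gam),
                   tolerance = 1e-12)
  }
})

test_that("louvain recovers planted cliques and is deterministic", {
  A <- two_cliques(5)
  p <- louvain_once(A, 1, seed = 3)
  expect_equal(n_modules(p), 2)
  expect_equal(p$assignment[1:5], rep(p$assignment[1], 5))
  expect_equal(p$q, brute_force_q_max(A, 1), tolerance = 1e-12)
  # complete graph: a single community is optimal
  K <- matrix(1, 8, 8) - diag(8)
  expect_equal(n_modules(louvain_once(K, 1, seed = 1)), 1)
  expect_lt(abs(louvain_once(K, 1, seed = 1)$q), 1e-12)
  # determinism contract
  set.seed(10)
  A2 <- random_weighted_graph(15)
  p1 <- louvain_once(A2, 1.3, seed = 99)
  p2 <- louvain_once(A2, 1.3, seed = 99)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("louvain never scores below the trivial partitions", {
  set.seed(17)
  for (rep in 1:15) {
    A <- random_weighted_graph(sample(5:10, 1))
    gam <- runif(1, 0.5, 2)
    p <- louvain_once(A, gam, seed = rep)
    q_single <- modularity_score(A, rep(1, nrow(A)), gam)
    q_singletons <- modularity_score(A, seq_len(nrow(A)), gam)
    expect_gte(p$q, q_single - 1e-12)
    expect_gte(p$q, q_singletons - 1e-12)
  }
})

test_that("best-of-restarts louvain reaches the exhaustive optimum on small graphs", {
  set.seed(31)
  hits <- 0
  n_graphs <- 20
  for (g in seq_len(n_graphs)) {
    n <- sample(5:8, 1)
    A <- random_weighted_graph(n)
    best <- max(vapply(1:50, function(r)
      louvain_once(A, 1, seed = derive_seed(g, r))$q, numeric(1)))
    if (abs(best - brute_force_q_max(A, 1)) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits / n_graphs, 0.95)
})

test_that("rand index and z-Rand match exhaustive pair counting and the permutation null", {
  # {A,B | C,D} vs {A,C | B,D}: 2 of 6 pairs concordant
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  # symmetry is exact
  set.seed(12)
  for (rep in 1:10) {
    p1 <- sample(1:4, 30, replace = TRUE)
    p2 <- sample(1:3, 30, replace = TRUE)
    expect_identical(zrand(p1, p2), zrand(p2, p1))
  }
  # self-similarity of a non-trivial partition exceeds chance
  expect_gt(zrand(rep(1:3, 10), rep(1:3, 10)), 0)
  # agreement with a Monte-Carlo permutation oracle
  set.seed(77)
  p1 <- c(rep(1, 15), rep(2, 15), rep(3, 10))
  p2 <- c(rep(1, 12), rep(2, 20), rep(3, 8))[sample(40)]
  z_mc <- zrand_perm_oracle(p1, p2, n_perm = 6000)
  expect_equal(zrand(p1, p2), z_mc, tolerance = 0.12)
  p3 <- c(rep(1, 20), rep(2, 20))
  z_mc3 <- zrand_perm_oracle(p3, rev(p3), n_perm = 6000)
  expect_equal(zrand(p3, rev(p3)), z_mc3, tolerance = 0.12)
})

test_that("z-Rand is centred at zero under independent random partitions", {
  set.seed(55)
  zs <- replicate(800, zrand(sample(rep(1:4, 15)), sample(rep(1:4, 15))))
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("gamma sweep bookkeeping: default grid has 26 levels, stability maximal on cliques", {
  A <- two_cliques(6)
  sw <- gamma_sweep(A, n_runs = 2, seed = 5, consensus = FALSE)
  expect_length(sw$gammas, 26)
  expect_equal(sw$gammas[1], 0.5)
  expect_equal(sw$gammas[26], 3, tolerance = 1e-12)
  # unique optimum at moderate resolutions: every run returns the clique
  # partition (large gamma legitimately splits cliques)
  planted <- rep(1:2, each = 6)
  low <- which(sw$gammas <= 1.4)
  for (g in low)
    expect_true(all(apply(sw$partitions[[g]], 2, rand_index, p2 = planted)
                    == 1))
  expect_equal(diff(range(sw$stability[low])), 0)
})

test_that("gamma selection maximizes stability with ties toward smaller gamma", {
  s <- structure(list(gammas = c(0.5, 1, 1.5), stability = c(0.2, 0.9, 0.4),
                      mean_q = c(0.5, 0.4, 0.3), selection = "stability"),
                 class = "sweep_result")
  expect_equal(select_gamma(s), 1)
  s$stability <- c(0.9, 0.9, 0.4)
  expect_equal(select_gamma(s), 0.5)
  expect_equal(select_gamma(s, selection = "max_q"), 0.5)
})

test_that("consensus partition reduces to its inputs in degenerate cases", {
  p <- rep(1:3, each = 5)
  # identical inputs return that partition
  cp <- consensus_partition(matrix(p, 15, 20), seed = 2)
  expect_equal(rand_index(cp, p), 1)
  # label permutations of one partition agree up to relabeling
  perms <- vapply(1:20, function(i) {
    map <- sample(1:3)
    map[p]
  }, integer(15))
  cp2 <- consensus_partition(perms, seed = 3)
  expect_equal(rand_index(cp2, p), 1)
})

test_that("consensus partition recovers a dominant partition against noise", {
  set.seed(41)
  p <- rep(1:4, each = 15)
  runs <- cbind(matrix(p, 60, 90),
                vapply(1:10, function(i) sample(1:4, 60, replace = TRUE),
                       integer(60)))
  cp <- consensus_partition(runs, seed = 9)
  expect_equal(rand_index(cp, p), 1)
})

test_that("planted-partition matrices are recovered at the selected resolution", {
  sp <- small_planted_spec(seed = 19)
  co <- generate_cohort_matrices(sp, seed = 19)
  cons <- consensus_weights(co, consensus_mask(co))
  sw <- gamma_sweep(cons$nos, gammas = seq(0.5, 3, by = 0.5), n_runs = 40,
                    seed = 23)
  expect_equal(rand_index(sw$consensus, co$planted), 1)
})
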