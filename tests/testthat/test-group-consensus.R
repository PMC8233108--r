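test_that("consensus mask applies the ceiling prevalence rule", {
  co <- hand_cohort()
  mask <- consensus_mask(co, 0.5)
  # edge (1,2) present in 2 of 4 subjects: threshold ceiling(0.5*4) = 2
  expect_true(mask[1, 2])
  # edge (1,3) present in all subjects: kept at any prevalence
  expect_true(consensus_mask(co, 1)[1, 3])
  # edge (3,4) present in 3 of 4: dropped at prevalence 1
  expect_false(consensus_mask(co, 1)[3, 4])
  expect_error(consensus_mask(cohort(co$subjects[0])), "empty")
  # the ceiling rule at the conventional cohort size: 35 subjects, 50%
  expect_equal(ceiling(0.5 * 35), 18)
})

test_that("raising prevalence never adds edges", {
  sp <- phantom_spec(n_regions = 25, n_subjects = 9, n_modules = 2)
  co <- generate_cohort_matrices(sp, seed = 4)
  prev <- seq(0.2, 1, by = 0.2)
  masks <- lapply(prev, function(p) consensus_mask(co, p))
  for (k in seq_along(prev)[-1])
    expect_true(all(masks[[k]] <= masks[[k - 1]]))
})

test_that("consensus weights take presence-only medians", {
  co <- hand_cohort()
  cons <- consensus_weights(co, consensus_mask(co, 0.5))
  # subject weights on (1,2): 0, 3, 5, 0 -> median over {3, 5} = 4
  expect_equal(cons$nos$weights[1, 2], 4)
  # subject weights on (3,4): 2, 100, 4, 0 -> median over {2, 100, 4} = 4,
  # robust to the outlier
  expect_equal(cons$nos$weights[3, 4], 4)
  # scalar medians follow the same rule
  expect_equal(cons$scalar$weights[1, 2], median(c(1.20, 1.10)))
  # weight lies within the across-subject min/max on every kept edge
  for (kind in c("nos", "scalar")) {
    stack <- vapply(co$subjects, function(s) s[[kind]]$weights,
                    matrix(0, 4, 4))
    w <- cons[[kind]]$weights
    for (idx in which(w != 0)) {
      ij <- arrayInd(idx, c(4, 4))
      vals <- stack[ij[1], ij[2], ]
      vals <- vals[vals != 0]
      expect_gte(w[idx], min(vals))
      expect_lte(w[idx], max(vals))
    }
  }
  # identical subjects: consensus equals any single subject on the mask
  same <- cohort(co$subjects[c(2, 2, 2)])
  cs <- consensus_weights(same, consensus_mask(same, 0.5))
  expect_equal(cs$nos$weights, co$subjects[[2]]$nos$weights)
})

test_that("edge regression matches hand-computed OLS", {
  nodes <- paste0("n", 1:3)
  mk <- function(v12, v13, v23, kind = "scalar") {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- v12
    m[1, 3] <- m[3, 1] <- v13
    m[2, 3] <- m[3, 2] <- v23
    connectome(m, kind, nodes)
  }
  b <- mk(1, 2, 3)
  a <- mk(2 * 1 + 1, 2 * 2 + 1, 2 * 3 + 1)
  fit <- suppressWarnings(edge_regression(a, b)) # lm warns on perfect fits
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$n_edges, 3)
  # points (1,1), (2,2), (3,2): hand OLS gives R^2 = 0.75
  fit2 <- edge_regression(mk(1, 2, 2), mk(1, 2, 3))
  expect_equal(fit2$r_squared, 0.75)
  # constant response: R^2 = 0
  fit3 <- edge_regression(mk(5, 5, 5), b)
  expect_equal(fit3$r_squared, 0)
  # zero-variance predictor is degenerate
  expect_error(edge_regression(b, mk(5, 5, 5)), "zero variance")
  # fewer than 3 common edges
  expect_error(edge_regression(mk(1, 2, 0), mk(1, 0, 2)), "3 common edges")
})

test_that("R-squared is symmetric in the two connectomes", {
  set.seed(8)
  n <- 12
  for (rep in 1:5) {
    m1 <- random_weighted_graph(n, 0.7)
    m2 <- random_weighted_graph(n, 0.7)
    both <- (m1 != 0) & (m2 != 0)
    m1[!both] <- 0
    m2[!both] <- 0
    if (sum(both[upper.tri(both)]) < 3) next
    a <- connectome(m1, "scalar")
    b <- connectome(m2, "scalar")
    expect_equal(edge_regression(a, b)$r_squared,
                 edge_regression(b, a)$r_squared, tolerance = 1e-12)
  }
})
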