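test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(lambda_within = 2, lambda_between = 2),
               "lambda_within > lambda_between")
  expect_error(phantom_spec(edge_prob_within = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(n_regions = 10,
                            planted_partition = c(rep(1, 5), rep(3, 5))),
               "contiguous")
  sp <- phantom_spec(n_regions = 14, n_modules = 2)
  expect_identical(sp$planted_partition, rep(1:2, each = 7L))
  expect_true(all(c("functional", "cyto") %in% names(sp$class_map)))
})

test_that("cohorts are reproducible, symmetric, and co-supported", {
  sp <- phantom_spec(n_regions = 20, n_subjects = 4, n_modules = 2)
  a <- generate_cohort_matrices(sp, seed = 5)
  b <- generate_cohort_matrices(sp, seed = 5)
  expect_identical(a$subjects, b$subjects)
  d <- generate_cohort_matrices(sp, seed = 6)
  expect_false(identical(a$subjects, d$subjects))
  for (s in a$subjects) {
    w <- s$nos$weights
    v <- s$scalar$weights
    expect_identical(w, t(w))
    expect_identical(diag(w), setNames(rep(0, 20), a$nodes))
    expect_identical(w != 0, v != 0)
    expect_true(all(w == round(w) & w >= 0))
    expect_true(all(v[v != 0] > 0 & v[v != 0] < 3))
  }
})

test_that("no between-module generation yields block-diagonal matrices", {
  sp <- phantom_spec(n_regions = 12, n_subjects = 3, n_modules = 3,
                     lambda_within = 5, lambda_between = 0,
                     edge_prob_between = 0)
  co <- generate_cohort_matrices(sp, seed = 2)
  blocks <- outer(sp$planted_partition, sp$planted_partition, "==")
  for (s in co$subjects)
    expect_true(all(s$nos$weights[!blocks] == 0))
})

test_that("degenerate noise gives exactly the base scalar on every edge", {
  eff0 <- setNames(rep(0, 7), c("VIS", "SM", "DA", "VA", "LIM", "FP", "DMN"))
  sp <- phantom_spec(n_regions = 15, n_subjects = 3, n_modules = 3,
                     scalar_class_effect = eff0, scalar_noise_sd = 0,
                     scalar_base = 1.1)
  co <- generate_cohort_matrices(sp, seed = 3)
  for (s in co$subjects) {
    v <- s$scalar$weights
    expect_true(all(v[v != 0] == 1.1))
  }
})

test_that("empirical mean NOS matches the generating rate", {
  # Monte-Carlo check: with lambda_within = 20 the truncated Poisson mean is
  # lambda / (1 - exp(-lambda)) ~ 20, and the subject-level log-normal rate
  # fluctuation is mean-preserving, so the pooled within-module mean should
  # land within 3 standard errors of 20.
  sp <- small_planted_spec(seed = 7)
  co <- generate_cohort_matrices(sp, seed = 7)
  blocks <- outer(sp$planted_partition, sp$planted_partition, "==")
  vals <- unlist(lapply(co$subjects, function(s) {
    w <- s$nos$weights[blocks & upper.tri(blocks)]
    w[w > 0]
  }))
  expected <- 20 / (1 - exp(-20))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("subject dropout leaves the consensus rule signal to act on", {
  sp <- phantom_spec(n_regions = 30, n_subjects = 20, n_modules = 2,
                     subject_keep = 0.8)
  co <- generate_cohort_matrices(sp, seed = 11)
  present <- Reduce(`+`, lapply(co$subjects,
                                function(s) s$nos$weights != 0))
  tmpl <- co$template & upper.tri(co$template)
  counts <- present[tmpl]
  # with keep = 0.8 over 20 subjects, template edges appear in some but
  # rarely all subjects
  expect_true(any(counts < 20))
  expect_true(all(counts <= 20))
  expect_gt(mean(counts / 20), 0.6)
})
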