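test_that("descending ranks with average ties", {
  expect_equal(unname(rank_nodes(c(10, 30, 20))), c(3, 1, 2))
  expect_equal(unname(rank_nodes(c(5, 5, 1))), c(1.5, 1.5, 3))
  # sign reversal reverses the order (tie-free case)
  set.seed(6)
  v <- rnorm(25)
  expect_equal(unname(rank_nodes(-v)), 26 - unname(rank_nodes(v)))
  expect_error(rank_nodes(c(1, NA, 3)), "undefined")
})

test_that("rank-difference z-scores match hand computation", {
  rz <- rank_difference_z(setNames(c(1, 2, 3, 4), letters[1:4]),
                          setNames(c(4, 3, 2, 1), letters[1:4]))
  expect_equal(rz$d, c(-3, -1, 1, 3))
  sdd <- sqrt(20 / 3)
  expect_equal(rz$z, c(-3, -1, 1, 3) / sdd, tolerance = 1e-12)
  # identical orderings give all-zero z
  same <- rank_difference_z(1:5, 1:5)
  expect_equal(same$z, rep(0, 5))
})

test_that("rank identities: zero-mean differences, unit-SD z", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    a <- rank_nodes(setNames(sample(n) + runif(n, -0.2, 0.2),
                             paste0("n", 1:n)))
    b <- rank_nodes(setNames(sample(n) + runif(n, -0.2, 0.2),
                             paste0("n", 1:n)))
    rz <- rank_difference_z(a, b)
    expect_equal(mean(rz$d), 0, tolerance = 1e-12)
    expect_equal(mean(rz$z), 0, tolerance = 1e-12)
    if (sd(rz$d) > 0) expect_equal(sd(rz$z), 1, tolerance = 1e-12)
    # swapping the connectomes flips the sign of z
    rz2 <- rank_difference_z(b, a)
    expect_equal(rz2$z, -rz$z, tolerance = 1e-12)
  }
})

test_that("class medians aggregate the right nodes and warn on empty classes", {
  classes <- data.frame(node = paste0("n", 1:6),
                        functional = c("VIS", "VIS", "DMN", "DMN", "FP",
                                       "FP"),
                        cyto = rep(c("PM", "ASC1"), 3))
  z <- setNames(c(-1, 0, 2, 1, -2, 3), paste0("n", 1:6))
  med <- class_median_z(z, classes, "functional")
  expect_equal(med[["VIS"]], -0.5)
  expect_equal(med[["DMN"]], 1.5)
  expect_equal(med[["FP"]], 0.5)
  # one class covering all nodes is the global median
  cls1 <- data.frame(node = paste0("n", 1:6), functional = "DMN",
                     cyto = "PM")
  expect_equal(unname(class_median_z(z, cls1, "functional")), median(z))
  # a class with z values {-1, 0, 2} has median 0
  expect_equal(unname(class_median_z(setNames(c(-1, 0, 2), paste0("n", 1:3)),
                                     cls1[1:3, ], "functional")), 0)
  # empty class warned and omitted
  sub <- z[1:4]
  expect_warning(m2 <- class_median_z(sub, classes, "functional"), "FP")
  expect_false("FP" %in% names(m2))
})

test_that("module-by-class composition is a proper contingency table", {
  classes <- data.frame(node = paste0("n", 1:9),
                        functional = rep(c("VIS", "SM", "DMN"), 3),
                        cyto = rep(c("PM", "ASC1", "LIM"), each = 3))
  p <- partition(rep(1:3, each = 3), nodes = paste0("n", 1:9))
  tab <- module_class_composition(p, classes, "functional")
  expect_equal(unname(rowSums(tab)), c(3, 3, 3))
  expect_equal(sum(tab), 9)
  # modules orthogonal to classes: every module spans >= 2 classes
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) >= 2))
  # partition identical to class assignment: diagonal table
  p2 <- partition(rep(1:3, 3), nodes = paste0("n", 1:9))
  tab2 <- module_class_composition(p2, classes, "functional")
  expect_equal(unname(diag(tab2)), c(3, 3, 3))
  expect_equal(sum(tab2) - sum(diag(tab2)), 0)
  # one module: the row equals the global class counts
  p3 <- partition(rep(1, 9), nodes = paste0("n", 1:9))
  expect_equal(as.numeric(module_class_composition(p3, classes,
                                                   "functional")),
               as.numeric(table(factor(classes$functional,
                                       levels = c("VIS", "SM", "DMN")))))
})

test_that("a planted transmodal scalar advantage yields negative transmodal medians", {
  sp <- small_planted_spec(seed = 29)
  co <- generate_cohort_matrices(sp, seed = 29)
  cons <- consensus_weights(co, consensus_mask(co))
  rk <- rank_comparison(cons$nos, cons$scalar, co$classes)
  trans <- c("DA", "VA", "LIM", "FP", "DMN")
  uni <- c("VIS", "SM")
  # transmodal classes rank better (numerically smaller) under the scalar
  # weighting, hence negative medians under d = rank_scalar - rank_nos
  expect_lt(median(rk$functional[trans]), 0)
  expect_gt(median(rk$functional[uni]), 0)
})
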