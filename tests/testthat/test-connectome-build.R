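# A tiny constructed phantom: three regions on a line, 1 mm voxels,
# single-voxel corridors, streamlines along the x axis.
toy_phantom <- function(v_ab = 1.2, v_bc = 1.0, base = 1.1) {
  dims <- c(61, 5, 5)
  lab <- array(0L, dims)
  lab[1:3, 3, 3] <- 1L    # region A near x = 0..2
  lab[30:32, 3, 3] <- 2L  # region B near x = 29..31
  lab[59:61, 3, 3] <- 3L  # region C near x = 58..60
  scal <- array(base, dims)
  scal[4:29, 3, 3] <- v_ab
  scal[33:58, 3, 3] <- v_bc
  aff <- diag(4)
  line <- function(x0, x1) {
    xs <- seq(x0, x1, by = 1)
    cbind(xs, rep(2, length(xs)), rep(2, length(xs)))
  }
  list(labels = label_volume(lab, aff),
       scalar = scalar_volume(scal, aff),
       tract = tractogram(list(line(1, 30), line(2, 29), line(1, 29),
                               line(31, 59))))
}

test_that("build_connectome counts bundles and thresholds both outputs", {
  ph <- toy_phantom()
  bc <- build_connectome(ph$tract, ph$labels, ph$scalar,
                         min_streamlines = 2, length_bounds = c(20, 250),
                         radius_mm = 0, mode = "nearest")
  expect_equal(bc$nos$weights[1, 2], 3)
  expect_equal(bc$nos$weights[2, 3], 0) # single streamline falls below 2
  expect_identical(edge_support(bc$nos), edge_support(bc$scalar))
  # pooled samples of the A-B bundle are dominated by the corridor value
  expect_equal(bc$scalar$weights[1, 2], 1.2)

  bc1 <- build_connectome(ph$tract, ph$labels, ph$scalar,
                          min_streamlines = 1, radius_mm = 0,
                          mode = "nearest")
  expect_equal(bc1$nos$weights[2, 3], 1)
  expect_equal(bc1$scalar$weights[2, 3], 1.0)
})

test_that("raising min_streamlines never adds edges", {
  ph <- toy_phantom()
  bc2 <- build_connectome(ph$tract, ph$labels, ph$scalar,
                          min_streamlines = 2, radius_mm = 0,
                          mode = "nearest")
  bc5 <- build_connectome(ph$tract, ph$labels, ph$scalar,
                          min_streamlines = 5, radius_mm = 0,
                          mode = "nearest")
  expect_true(all(edge_support(bc5$nos) <= edge_support(bc2$nos)))
  expect_equal(sum(bc5$nos$weights), 0) # all bundles have fewer than 5
})

test_that("median conventions: odd count direct, even count midpoint", {
  expect_equal(median(c(1.0, 1.2, 1.1)), 1.1)
  ph <- toy_phantom()
  bc <- build_connectome(ph$tract, ph$labels, ph$scalar,
                         min_streamlines = 1, radius_mm = 0,
                         mode = "nearest")
  # scalar weight lies within the pooled sample range of its bundle
  sm_ab <- unlist(lapply(ph$tract$streamlines[1:3], sample_scalar,
                         vol = ph$scalar, mode = "nearest"))
  expect_gte(bc$scalar$weights[1, 2], min(sm_ab))
  expect_lte(bc$scalar$weights[1, 2], max(sm_ab))
  expect_equal(bc$scalar$weights[1, 2], median(sm_ab))
})

test_that("per-streamline pooling switch changes the median convention", {
  ph <- toy_phantom()
  pooled <- build_connectome(ph$tract, ph$labels, ph$scalar,
                             min_streamlines = 1, radius_mm = 0,
                             mode = "nearest", pooling = "pooled")
  per <- build_connectome(ph$tract, ph$labels, ph$scalar,
                          min_streamlines = 1, radius_mm = 0,
                          mode = "nearest", pooling = "per_streamline")
  sm <- lapply(ph$tract$streamlines[1:3], sample_scalar,
               vol = ph$scalar, mode = "nearest")
  expect_equal(per$scalar$weights[1, 2],
               median(vapply(sm, median, numeric(1))))
  expect_equal(pooled$scalar$weights[1, 2], median(unlist(sm)))
})

test_that("a tractogram with no assignable streamlines warns and zeroes", {
  ph <- toy_phantom()
  far <- tractogram(list(rbind(c(0, 200, 200), c(40, 200, 200))))
  expect_warning(
    bc <- build_connectome(far, ph$labels, ph$scalar, min_streamlines = 1),
    "no assignable")
  expect_equal(sum(bc$nos$weights), 0)
})

test_that("geometry-mode phantom reproduces planted counts and medians", {
  sp <- phantom_spec(n_regions = 6, n_subjects = 1, n_modules = 2,
                     lambda_within = 3, lambda_between = 2,
                     edge_prob_within = 1, edge_prob_between = 1,
                     scalar_noise_sd = 0, seed = 7)
  g <- generate_phantom_geometry(sp, seed = 7)
  expect_true(all(streamline_lengths(g$tractogram) >= 20))
  expect_true(all(streamline_lengths(g$tractogram) <= 250))
  bc <- build_connectome(g$tractogram, g$labels, g$scalar,
                         min_streamlines = 1, mode = "nearest")
  for (r in seq_len(nrow(g$truth))) {
    i <- g$truth$i[r]
    j <- g$truth$j[r]
    expect_equal(unname(bc$nos$weights[i, j]), g$truth$nos[r])
    expect_equal(unname(bc$scalar$weights[i, j]), g$truth$v_planted[r])
  }
  # reproducibility of the full geometry product
  g2 <- generate_phantom_geometry(sp, seed = 7)
  expect_identical(g$scalar$grid, g2$scalar$grid)
  expect_identical(g$tractogram$streamlines, g2$tractogram$streamlines)
})
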