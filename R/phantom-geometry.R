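# Phantom geometry: compact spherical regions connected by arc-shaped
# streamline corridors. The placement (region centres + one bulged arc per
# region pair) is found by a deterministic repair search that guarantees:
#   * every pair of corridors is separated by > `segsep` mm outside guard
#     balls of radius `guard` around shared endpoints,
#   * no corridor passes within `csep` mm of a non-incident region centre,
#   * every arc is at least `len_min` mm and at most 250 mm long.
# Together with the painting rule (corridor radius `paint_r`, no painting
# within `paint_excl` mm of any centre) this makes every painted voxel
# attributable to exactly one bundle, and guarantees that a strict majority
# of each streamline's samples take the bundle's planted value — so the
# noise-free pooled median is exact by construction.
#
# The search uses its own fixed seed sequence, independent of the user seed:
# geometry placement is a property of the phantom design, whereas the user
# seed drives edges, counts, jitter and noise.

geom_const <- list(spacing = 64, jitter = 4, offset = 48,
                   segsep = 6.5, csep = 15, guard = 9,
                   hmax = 34, len_min = 72, len_max = 245,
                   box = c(6, 154),
                   paint_r = 3, paint_excl = 12, label_r = 5,
                   max_regions = 8)

.placement_cache <- new.env(parent = emptyenv())

# Evaluate the sine-bulge arc between A and B at ~`step` mm chord spacing.
arc_points <- function(A, B, phi, h, step = 0.5) {
  u <- B - A
  L <- sqrt(sum(u^2))
  u <- u / L
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- a - sum(a * u) * u
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  d <- cos(phi) * n1 + sin(phi) * n2
  np <- max(3, ceiling(L / step))
  tt <- seq(0, 1, length.out = np)
  sweep(outer(tt, B - A), 2, A, "+") + (h * sin(pi * tt)) %o% d
}

arc_len <- function(X) sum(sqrt(rowSums(diff(X)^2)))

min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# Smallest bulge giving at least the target arc length.
bulge_for_length <- function(A, B, phi, target) {
  for (h in seq(0, 40, by = 2))
    if (arc_len(arc_points(A, B, phi, h, step = 1)) >= target) return(h)
  40
}

placement_search <- function(n_regions, maxit = 20000, n_seeds = 8) {
  key <- as.character(n_regions)
  hit <- .placement_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- geom_const
  if (n_regions < 2 || n_regions > g$max_regions)
    stop_param("geometry mode supports 2-", g$max_regions, " regions")
  for (s in seq_len(n_seeds)) {
    res <- with_seed(1000003L + s, placement_attempt(n_regions, maxit))
    if (!is.null(res)) {
      .placement_cache[[key]] <- res
      return(res)
    }
  }
  stop_param("could not place ", n_regions,
             " regions with separated corridors (geometry error)")
}

placement_attempt <- function(R, maxit) {
  g <- geom_const
  ncell <- ceiling(R^(1 / 3))
  grid <- as.matrix(expand.grid(0:(ncell - 1), 0:(ncell - 1),
                                0:(ncell - 1))) * g$spacing
  cells <- grid[order(rowSums(grid * c(1, 1.01, 1.02)))[seq_len(R)], ,
                drop = FALSE]
  P <- cells + matrix(stats::runif(R * 3, -g$jitter, g$jitter), R, 3) +
    g$offset
  D <- as.matrix(stats::dist(P))
  if (min(D[upper.tri(D)]) < 40) return(NULL)
  pairs <- t(utils::combn(R, 2))
  np <- nrow(pairs)
  resample <- function(k) {
    phi <- stats::runif(1, 0, 2 * pi)
    A <- P[pairs[k, 1], ]
    B <- P[pairs[k, 2], ]
    hlo <- bulge_for_length(A, B, phi, g$len_min)
    h <- stats::runif(1, hlo, max(hlo + 2, g$hmax))
    list(phi = phi, h = h, arc = arc_points(A, B, phi, h))
  }
  st <- lapply(seq_len(np), resample)
  arcs <- lapply(st, `[[`, "arc")
  bad_centre <- function(k) {
    others <- setdiff(seq_len(R), pairs[k, ])
    (length(others) > 0 &&
       min_cross_dist(arcs[[k]], P[others, , drop = FALSE]) < g$csep) ||
      min(arcs[[k]]) < g$box[1] || max(arcs[[k]]) > g$box[2] ||
      arc_len(arcs[[k]]) > g$len_max
  }
  bad_pair <- function(a, b) {
    sh <- intersect(pairs[a, ], pairs[b, ])
    A <- arcs[[a]]
    B <- arcs[[b]]
    if (length(sh) == 1) {
      c0 <- P[sh, ]
      A <- A[sqrt(rowSums((A - matrix(c0, nrow(A), 3, byrow = TRUE))^2)) >
               g$guard, , drop = FALSE]
      B <- B[sqrt(rowSums((B - matrix(c0, nrow(B), 3, byrow = TRUE))^2)) >
               g$guard, , drop = FALSE]
    }
    nrow(A) > 0 && nrow(B) > 0 && min_cross_dist(A, B) < g$segsep
  }
  cv <- vapply(seq_len(np), bad_centre, logical(1))
  pv <- matrix(FALSE, np, np)
  if (np > 1)
    for (a in seq_len(np - 1)) for (b in (a + 1):np) pv[a, b] <- bad_pair(a, b)
  for (it in seq_len(maxit)) {
    vset <- unique(c(which(cv), as.vector(which(pv, arr.ind = TRUE))))
    if (!length(vset)) {
      return(list(centres = P, pairs = pairs,
                  phi = vapply(st, `[[`, numeric(1), "phi"),
                  h = vapply(st, `[[`, numeric(1), "h")))
    }
    k <- if (length(vset) == 1) vset else vset[sample.int(length(vset), 1)]
    st[[k]] <- resample(k)
    arcs[[k]] <- st[[k]]$arc
    cv[k] <- bad_centre(k)
    for (b in setdiff(seq_len(np), k)) {
      a2 <- min(k, b)
      b2 <- max(k, b)
      pv[a2, b2] <- bad_pair(a2, b2)
    }
  }
  NULL
}

#' Generate full phantom geometry with known ground truth
#'
#' Produces a parcellation label volume (compact spherical regions), a
#' scalar volume (constant planted value along each bundle corridor on a
#' `scalar_base` background, plus optional voxel-wise Gaussian noise) and a
#' tractogram of jittered arc-shaped streamlines whose endpoints lie inside
#' their intended regions, with per-pair streamline counts drawn by the same
#' template/truncated-Poisson model as [generate_cohort_matrices()]. All
#' streamline lengths fall within the conventional 20-250 mm filter window.
#'
#' Region placement and corridor routing are deterministic properties of
#' `n_regions` (found once by an internal search); the seed drives which
#' pairs carry bundles, the streamline counts, the vertex jitter and the
#' scalar noise.
#'
#' @param spec a [phantom_spec()] with `n_regions` at most 8 and
#'   `grid_shape`/`voxel_size` covering at least 160 mm per axis.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `labels` ([label_volume()]), `scalar`
#'   ([scalar_volume()]), `tractogram` ([tractogram()]) and `truth`, a data
#'   frame with one row per realized bundle (`i`, `j`, `nos`,
#'   `v_planted`, `arc_length_mm`).
#' @export
generate_phantom_geometry <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- geom_const
  R <- spec$n_regions
  world_extent <- (spec$grid_shape - 1) * spec$voxel_size
  if (any(world_extent < g$box[2] + 4))
    stop_param("grid too small: regions cannot fit (geometry error)")
  pl <- placement_search(R)
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  dims <- spec$grid_shape

  # --- label volume: spherical regions around the centres
  centre_vox <- pl$centres / spec$voxel_size
  lab <- array(0L, dims)
  rad_vox <- ceiling(g$label_r / spec$voxel_size)
  for (r in seq_len(R)) {
    c0 <- centre_vox[r, ]
    rng <- lapply(1:3, function(a)
      max(0, floor(c0[a] - rad_vox)):min(dims[a] - 1, ceiling(c0[a] + rad_vox)))
    sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    d2 <- colSums((t(sub) * spec$voxel_size - pl$centres[r, ])^2)
    inside <- sub[d2 <= g$label_r^2, , drop = FALSE]
    lab[inside + 1] <- r
  }

  # --- planted edges and values
  pairs <- pl$pairs
  same_mod <- spec$planted_partition[pairs[, 1]] ==
    spec$planted_partition[pairs[, 2]]
  p_edge <- ifelse(same_mod, spec$edge_prob_within, spec$edge_prob_between)
  lambda0 <- ifelse(same_mod, spec$lambda_within, spec$lambda_between)
  eff <- spec$scalar_class_effect[spec$class_map$functional]
  v_planted <- spec$scalar_base + (eff[pairs[, 1]] + eff[pairs[, 2]]) / 2

  with_seed(derive_seed(seed, 31L), {
    exists_ <- stats::runif(nrow(pairs)) < p_edge
    nos <- integer(nrow(pairs))
    nos[exists_] <- rpois_trunc1(lambda0[exists_])

    # --- scalar volume: paint corridors of realized bundles
    scal <- array(spec$scalar_base, dims)
    owner <- array(0L, dims)
    for (k in which(exists_)) {
      arc <- arc_points(pl$centres[pairs[k, 1], ], pl$centres[pairs[k, 2], ],
                        pl$phi[k], pl$h[k], step = 0.5)
      vox <- corridor_voxels(arc, dims, spec$voxel_size, g$paint_r)
      if (!nrow(vox)) next
      xyz <- vox * spec$voxel_size
      dcen <- vapply(seq_len(R), function(r)
        sqrt(colSums((t(xyz) - pl$centres[r, ])^2)), numeric(nrow(xyz)))
      keep <- apply(matrix(dcen, nrow = nrow(xyz)), 1, min) > g$paint_excl
      vox <- vox[keep, , drop = FALSE]
      if (!nrow(vox)) next
      lin <- vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1
      clash <- owner[lin] != 0L & owner[lin] != k
      if (any(clash))
        stop_param("internal geometry error: corridor overlap detected")
      owner[lin] <- k
      scal[lin] <- v_planted[k]
    }
    if (spec$scalar_noise_sd > 0)
      scal <- scal + array(stats::rnorm(prod(dims), 0, spec$scalar_noise_sd),
                           dims)
    scal <- pmin(pmax(scal, 1e-6), 3 - 1e-6)

    # --- streamlines along the corridors
    sls <- list()
    arc_lengths <- numeric(nrow(pairs))
    for (k in which(exists_)) {
      A <- pl$centres[pairs[k, 1], ]
      B <- pl$centres[pairs[k, 2], ]
      arc <- arc_points(A, B, pl$phi[k], pl$h[k], step = 0.5)
      path <- resample_polyline(arc, step = 1)
      arc_lengths[k] <- arc_len(path)
      s_from_a <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
      s_from_b <- max(s_from_a) - s_from_a
      for (m in seq_len(nos[k])) {
        d0 <- runif_ball(2)
        d1 <- runif_ball(2)
        taper0 <- exp(-s_from_a / 4)
        taper1 <- exp(-s_from_b / 4)
        jit <- matrix(stats::runif(length(s_from_a) * 3, -0.17, 0.17),
                      ncol = 3)
        jit[c(1, nrow(jit)), ] <- 0 # endpoints exactly inside the regions
        sl <- path + outer(taper0, d0) + outer(taper1, d1) + jit
        sls[[length(sls) + 1]] <- sl
      }
    }
    truth <- data.frame(i = pairs[exists_, 1], j = pairs[exists_, 2],
                        nos = nos[exists_],
                        v_planted = unname(v_planted[exists_]),
                        arc_length_mm = arc_lengths[exists_])
    list(labels = label_volume(lab, affine,
                               stats::setNames(spec$class_map$node[seq_len(R)],
                                               seq_len(R))),
         scalar = scalar_volume(scal, affine),
         tractogram = tractogram(sls),
         truth = truth)
  })
}

# Voxel indices (0-based rows) whose centres lie within `radius` mm of any
# arc sample point.
corridor_voxels <- function(arc, dims, voxel_size, radius) {
  rv <- ceiling(radius / voxel_size)
  offs <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
  base <- round(arc / voxel_size)
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
    base + matrix(offs[o, ], nrow(base), 3, byrow = TRUE))))
  ok <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
    cand[, 1] <= dims[1] - 1 & cand[, 2] <= dims[2] - 1 &
    cand[, 3] <= dims[3] - 1
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  xyz <- cand * voxel_size
  # min distance to the arc, chunked over arc points
  dmin <- rep(Inf, nrow(xyz))
  chunk <- 64
  for (s in seq(1, nrow(arc), by = chunk)) {
    blk <- arc[s:min(nrow(arc), s + chunk - 1), , drop = FALSE]
    d2 <- outer(rowSums(xyz^2), rowSums(blk^2), "+") - 2 * xyz %*% t(blk)
    dmin <- pmin(dmin, sqrt(pmax(0, apply(d2, 1, min))))
  }
  cand[dmin <= radius, , drop = FALSE]
}

resample_polyline <- function(X, step = 1) {
  s <- c(0, cumsum(sqrt(rowSums(diff(X)^2))))
  L <- s[length(s)]
  snew <- unique(c(seq(0, L, by = step), L))
  cbind(stats::approx(s, X[, 1], xout = snew)$y,
        stats::approx(s, X[, 2], xout = snew)$y,
        stats::approx(s, X[, 3], xout = snew)$y)
}

runif_ball <- function(r) {
  repeat {
    v <- stats::runif(3, -r, r)
    if (sum(v^2) <= r^2) return(v)
  }
}
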