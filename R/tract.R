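#' Tractogram container
#'
#' A list of streamlines (each an n x 3 matrix of world-mm vertex
#' coordinates) sharing one spatial reference.
#'
#' @param streamlines list of numeric matrices with 3 columns; every
#'   streamline needs at least one vertex with finite coordinates.
#' @param space character id of the shared space (default `"world-mm"`).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, space = "world-mm") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3) stop_param("streamline vertices must be n x 3")
    if (nrow(s) < 1) stop_param("streamline needs at least one vertex")
    if (any(!is.finite(s))) stop_param("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, space = space),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  ns <- length(x$streamlines)
  if (ns) {
    lens <- streamline_lengths(x)
    cat(sprintf("<tractogram> %d streamlines, lengths %.1f-%.1f mm (space %s)\n",
                ns, min(lens), max(lens), x$space))
  } else cat(sprintf("<tractogram> empty (space %s)\n", x$space))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Streamline length in millimetres
#'
#' Sum of Euclidean segment lengths along the polyline; a single-vertex
#' streamline has length 0.
#'
#' @param s an n x 3 vertex matrix (world mm).
#' @return length in mm.
#' @export
streamline_length <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2) return(0)
  sum(sqrt(rowSums(diff(s)^2)))
}

#' @rdname streamline_length
#' @param t a `tractogram`.
#' @return for `streamline_lengths`, a numeric vector of lengths.
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, streamline_length, numeric(1))
}

#' Filter streamlines by length
#'
#' Keeps streamlines whose length lies in `[min_mm, max_mm]` (both bounds
#' inclusive: the conventional discard rule removes streamlines strictly
#' shorter than the lower bound or strictly longer than the upper one,
#' typically 20 and 250 mm). Order is preserved.
#'
#' @param t a `tractogram`.
#' @param min_mm,max_mm inclusive length bounds in mm.
#' @return a filtered `tractogram`.
#' @export
filter_by_length <- function(t, min_mm = 20, max_mm = 250) {
  if (min_mm < 0 || min_mm > max_mm)
    stop_param("need 0 <= min_mm <= max_mm")
  lens <- streamline_lengths(t)
  tractogram(t$streamlines[lens >= min_mm & lens <= max_mm], space = t$space)
}

#' Assign streamline endpoints to parcellation regions
#'
#' Each terminal vertex maps to the label of its containing voxel; if that
#' voxel is background (or outside the volume), the nearest labelled voxel
#' whose centre lies within `radius_mm` is used instead. The streamline is
#' unassigned if either endpoint fails, or if both endpoints map to the same
#' region (self-connections carry no edge).
#'
#' @param s an n x 3 vertex matrix (world mm).
#' @param labels a [label_volume()].
#' @param radius_mm search radius for the nearest-labelled-voxel fallback
#'   (0 = pure voxel containment).
#' @return integer vector `c(label_a, label_b)`, or `NULL` if unassigned.
#' @export
assign_endpoints <- function(s, labels, radius_mm = 2) {
  if (radius_mm < 0) stop_param("radius_mm must be >= 0")
  s <- as.matrix(s)
  ends <- s[c(1, nrow(s)), , drop = FALSE]
  la <- endpoint_label(ends[1, ], labels, radius_mm)
  lb <- endpoint_label(ends[2, ], labels, radius_mm)
  if (is.na(la) || is.na(lb) || la == lb) return(NULL)
  c(la, lb)
}

endpoint_label <- function(xyz, labels, radius_mm) {
  dims <- dim(labels$grid)
  v <- world_to_voxel(xyz, labels$affine)[1, ]
  ijk <- round(v)
  inside <- all(ijk >= 0) && all(ijk <= dims - 1)
  if (inside) {
    lab <- labels$grid[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
    if (lab > 0) return(lab)
  }
  if (radius_mm == 0) return(NA_integer_)
  cen <- labelled_voxel_centres(labels)
  d2 <- colSums((t(cen$xyz) - xyz)^2)
  j <- which.min(d2)
  if (length(j) && d2[j] <= radius_mm^2) cen$label[j] else NA_integer_
}

# Cache world coordinates of labelled voxel centres on the volume object's
# environment-free list (recomputed per call site via memo in attr).
labelled_voxel_centres <- function(labels) {
  memo <- attr(labels, ".centres", exact = TRUE)
  if (!is.null(memo)) return(memo)
  idx <- which(labels$grid > 0, arr.ind = TRUE)
  list(xyz = voxel_to_world(idx - 1, labels$affine),
       label = labels$grid[idx])
}

#' Sample a scalar volume along a streamline
#'
#' Returns one sample per vertex. With `mode = "nearest"` the value of the
#' containing voxel is used; with `mode = "trilinear"` the 8 surrounding
#' voxel centres are linearly interpolated. Vertices outside the volume (for
#' trilinear: outside the grid of voxel centres) contribute no sample.
#'
#' @param s an n x 3 vertex matrix (world mm).
#' @param vol a [scalar_volume()].
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return numeric vector of samples (possibly empty).
#' @export
sample_scalar <- function(s, vol, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  s <- as.matrix(s)
  dims <- dim(vol$grid)
  v <- world_to_voxel(s, vol$affine)
  if (mode == "nearest") {
    ijk <- round(v)
    ok <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
      ijk[, 1] <= dims[1] - 1 & ijk[, 2] <= dims[2] - 1 &
      ijk[, 3] <= dims[3] - 1
    ijk <- ijk[ok, , drop = FALSE]
    if (!nrow(ijk)) return(numeric(0))
    vol$grid[ijk + 1]
  } else {
    ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] <= dims[1] - 1 & v[, 2] <= dims[2] - 1 & v[, 3] <= dims[3] - 1
    v <- v[ok, , drop = FALSE]
    if (!nrow(v)) return(numeric(0))
    trilinear(vol$grid, v)
  }
}

trilinear <- function(grid, v) {
  dims <- dim(grid)
  f <- pmax(pmin(floor(v), matrix(rep(dims - 2, each = nrow(v)), ncol = 3)),
            0)
  d <- v - f
  out <- numeric(nrow(v))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) d[, 1] else 1 - d[, 1]) *
      (if (dy) d[, 2] else 1 - d[, 2]) *
      (if (dz) d[, 3] else 1 - d[, 3])
    # clamp corner indices into the grid; along singleton axes the weight of
    # the clamped corner is zero
    idx <- cbind(pmin(f[, 1] + dx, dims[1] - 1),
                 pmin(f[, 2] + dy, dims[2] - 1),
                 pmin(f[, 3] + dz, dims[3] - 1))
    out <- out + w * grid[idx + 1]
  }
  out
}
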