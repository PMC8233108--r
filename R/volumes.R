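#' Scalar and label volumes
#'
#' Thin containers pairing a 3-D grid with a voxel-to-world affine (RAS
#' millimetres, 0-based voxel indices, voxel centre at `affine %*% c(i,j,k,1)`).
#' A `scalar_volume` holds a continuous quantitative map (e.g. R1 in 1/s);
#' a `label_volume` holds integer region labels with 0 reserved for
#' background.
#'
#' @param grid 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; must be invertible.
#' @param label_table for label volumes, named character vector or data frame
#'   mapping label to region name; defaults to `"region<k>"` for the labels
#'   present.
#' @return an object of class `scalar_volume` or `label_volume`.
#' @export
scalar_volume <- function(grid, affine = diag(4)) {
  check_volume(grid, affine)
  structure(list(grid = grid, affine = affine), class = "scalar_volume")
}

#' @rdname scalar_volume
#' @export
label_volume <- function(grid, affine = diag(4), label_table = NULL) {
  check_volume(grid, affine)
  if (max(abs(grid - round(grid))) > 0)
    stop_param("label grid must be integer-valued")
  storage.mode(grid) <- "integer"
  labs <- sort(setdiff(unique(as.integer(grid)), 0L))
  if (any(labs < 0)) stop_param("labels must be non-negative (0 = background)")
  if (is.null(label_table))
    label_table <- stats::setNames(paste0("region", labs), labs)
  structure(list(grid = grid, affine = affine, label_table = label_table),
            class = "label_volume")
}

check_volume <- function(grid, affine) {
  if (length(dim(grid)) != 3) stop_param("grid must be a 3-D array")
  if (!identical(dim(affine), c(4L, 4L))) stop_param("affine must be 4x4")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop_param("affine is singular")
  invisible(TRUE)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, values [%.4g, %.4g]\n",
              paste(dim(x$grid), collapse = "x"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d labels (+ background)\n",
              paste(dim(x$grid), collapse = "x"),
              length(x$label_table)))
  invisible(x)
}

# world (n x 3, mm) -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

# 0-based voxel coordinates -> world mm
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}
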