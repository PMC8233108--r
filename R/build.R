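#' Build paired NOS- and scalar-weighted connectomes for one subject
#'
#' Streamlines are length-filtered, endpoint-assigned to regions, and grouped
#' into bundles (one per region pair). Per bundle the NOS weight is the
#' streamline count and the scalar weight is the median of the scalar samples
#' pooled over all the bundle's streamlines ("one median per bundle"; the
#' median of per-streamline medians is available via
#' `pooling = "per_streamline"` for sensitivity analysis). Pairs with fewer
#' than `min_streamlines` streamlines are zeroed in both outputs, so the two
#' matrices always share their edge support. Bundles whose pooled sample list
#' is empty (all vertices outside the scalar volume) are dropped from both.
#'
#' @param t a [tractogram()] in world mm.
#' @param labels a [label_volume()] in the same space.
#' @param scalar a [scalar_volume()] in the same space.
#' @param min_streamlines minimum streamline count per retained edge
#'   (default 2; 5 is the conservative robustness setting).
#' @param length_bounds inclusive length filter in mm (default `c(20, 250)`).
#' @param radius_mm endpoint-assignment search radius, see
#'   [assign_endpoints()].
#' @param mode scalar sampling mode, see [sample_scalar()].
#' @param pooling `"pooled"` (default) or `"per_streamline"` median
#'   convention.
#' @return list with elements `nos` and `scalar`, both [connectome()]s over
#'   the label table's regions.
#' @export
build_connectome <- function(t, labels, scalar, min_streamlines = 2,
                             length_bounds = c(20, 250), radius_mm = 2,
                             mode = c("trilinear", "nearest"),
                             pooling = c("pooled", "per_streamline")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  if (min_streamlines < 1) stop_param("min_streamlines must be >= 1")
  region_labels <- as.integer(names(labels$label_table))
  n <- length(region_labels)
  nodes <- unname(unlist(labels$label_table))
  t <- filter_by_length(t, length_bounds[1], length_bounds[2])

  counts <- matrix(0L, n, n)
  samples <- vector("list", n * n)
  for (sl in t$streamlines) {
    ends <- assign_endpoints(sl, labels, radius_mm)
    if (is.null(ends)) next
    i <- match(ends[1], region_labels)
    j <- match(ends[2], region_labels)
    if (is.na(i) || is.na(j)) next
    if (i > j) { k <- i; i <- j; j <- k }
    counts[i, j] <- counts[i, j] + 1L
    sm <- sample_scalar(sl, scalar, mode)
    key <- (j - 1) * n + i
    if (pooling == "pooled") {
      samples[[key]] <- c(samples[[key]], sm)
    } else if (length(sm)) {
      samples[[key]] <- c(samples[[key]], stats::median(sm))
    }
  }
  if (sum(counts) == 0)
    warning("no assignable streamlines; returning empty connectomes")

  nosw <- matrix(0, n, n)
  sclw <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- counts[i, j]
    if (cnt < min_streamlines) next
    sm <- samples[[(j - 1) * n + i]]
    if (!length(sm)) next # no scalar weight definable: drop from both
    nosw[i, j] <- nosw[j, i] <- cnt
    sclw[i, j] <- sclw[j, i] <- stats::median(sm)
  }
  prov <- list(min_streamlines = min_streamlines,
               length_bounds = length_bounds, radius_mm = radius_mm,
               mode = mode, pooling = pooling,
               n_streamlines_used = sum(counts))
  list(nos = connectome(nosw, "nos", nodes, provenance = prov),
       scalar = connectome(sclw, "scalar", nodes, provenance = prov))
}
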