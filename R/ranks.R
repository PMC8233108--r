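#' Descending node ranks
#'
#' Rank 1 is the largest value; ties receive the average of the spanned
#' ranks. Undefined (`NA`) values are an error — callers must exclude or
#' flag isolated nodes first.
#'
#' @param values a `node_metric` or numeric vector.
#' @return numeric rank vector (named like the input).
#' @export
rank_nodes <- function(values) {
  v <- as.numeric(values)
  names(v) <- names(values)
  if (anyNA(v))
    stop_param("undefined values present; exclude isolated nodes first")
  rank(-v, ties.method = "average")
}

#' Rank-difference z-scores between two weightings
#'
#' Per node, the difference `d = rank_scalar - rank_nos` (rank 1 = highest)
#' is z-scored across nodes with the sample SD. With tie-free inputs the
#' differences sum to zero exactly, so z has mean 0 and sample SD 1. A node
#' that ranks better (numerically smaller) under the scalar weighting than
#' under NOS therefore gets a negative z. If every difference is zero, z is
#' zero everywhere.
#'
#' @param rank_scalar,rank_nos rank vectors over the same nodes (from
#'   [rank_nodes()]).
#' @return data frame with columns `node`, `rank_scalar`, `rank_nos`, `d`,
#'   `z`.
#' @export
rank_difference_z <- function(rank_scalar, rank_nos) {
  if (length(rank_scalar) != length(rank_nos))
    stop_param("rank vectors must cover the same nodes")
  if (length(rank_scalar) < 2) stop_param("need at least 2 nodes")
  nodes <- names(rank_scalar)
  if (is.null(nodes)) nodes <- as.character(seq_along(rank_scalar))
  if (!is.null(names(rank_nos)) && !identical(nodes, names(rank_nos)))
    stop_param("rank vectors must cover the same nodes in the same order")
  d <- as.numeric(rank_scalar) - as.numeric(rank_nos)
  s <- stats::sd(d)
  z <- if (s == 0) rep(0, length(d)) else (d - mean(d)) / s
  data.frame(node = nodes, rank_scalar = as.numeric(rank_scalar),
             rank_nos = as.numeric(rank_nos), d = d, z = z,
             stringsAsFactors = FALSE)
}

#' Median rank-difference z-score per node class
#'
#' @param z per-node z-scores: either the data frame from
#'   [rank_difference_z()] or a named numeric vector.
#' @param classes class map data frame (`node`, `functional`, `cyto`).
#' @param scheme `"functional"` or `"cyto"`.
#' @return named numeric vector of class medians (classes without nodes are
#'   omitted with a warning).
#' @export
class_median_z <- function(z, classes, scheme = c("functional", "cyto")) {
  scheme <- match.arg(scheme)
  if (is.data.frame(z)) z <- stats::setNames(z$z, z$node)
  cls <- classes[[scheme]][match(names(z), classes$node)]
  if (anyNA(cls)) stop_param("some nodes are not classed in scheme ", scheme)
  all_classes <- unique(classes[[scheme]])
  empty <- setdiff(all_classes, unique(cls))
  if (length(empty))
    warning("empty class(es) omitted: ", paste(empty, collapse = ", "))
  med <- tapply(as.numeric(z), cls, stats::median)
  stats::setNames(as.numeric(med), names(med))
}

#' Module-by-class composition table
#'
#' Contingency table counting how many nodes of each class fall in each
#' module; row sums equal module sizes, the grand total is the node count.
#'
#' @param p a [partition()] (or assignment vector) over the classed nodes.
#' @param classes class map data frame (`node`, `functional`, `cyto`).
#' @param scheme `"functional"` or `"cyto"`.
#' @return a `table` (modules x classes).
#' @export
module_class_composition <- function(p, classes,
                                     scheme = c("functional", "cyto")) {
  scheme <- match.arg(scheme)
  ci <- partition_vec(p)
  nodes <- names(ci)
  cls <- if (is.null(nodes)) classes[[scheme]]
         else classes[[scheme]][match(nodes, classes$node)]
  if (length(cls) != length(ci) || anyNA(cls))
    stop_param("partition and class map must cover the same nodes")
  table(module = paste0("M", ci),
        class = factor(cls, levels = unique(classes[[scheme]])))
}

#' Rank comparison of the two weightings of one network pair
#'
#' Convenience wrapper: computes NOS strength and the scalar-weighted
#' average on consensus networks, ranks both, z-scores the rank differences
#' and aggregates them by class.
#'
#' @param nos,scalar consensus [connectome()]s sharing support.
#' @param classes class map data frame.
#' @param flip_sign negate z (presentation convention: with the default
#'   `FALSE`, classes that rank better under the scalar weighting have
#'   negative medians).
#' @return object of class `rank_comparison`: list with `nodes` (per-node
#'   data frame), `functional` and `cyto` class medians.
#' @export
rank_comparison <- function(nos, scalar, classes, flip_sign = FALSE) {
  s_nos <- nos_strength(nos)
  s_r1 <- weighted_average(nos, scalar)
  keep <- !is.na(s_r1)
  rz <- rank_difference_z(rank_nodes(s_r1[keep]),
                          rank_nodes(s_nos[keep]))
  if (flip_sign) rz$z <- -rz$z
  structure(list(nodes = rz,
                 functional = class_median_z(rz, classes, "functional"),
                 cyto = class_median_z(rz, classes, "cyto"),
                 flip_sign = flip_sign),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison> %d nodes (sign: negative = better %s rank)\n",
              nrow(x$nodes),
              if (x$flip_sign) "NOS" else "scalar"))
  cat("functional class medians:\n")
  print(round(x$functional, 3))
  cat("cytoarchitectonic class medians:\n")
  print(round(x$cyto, 3))
  invisible(x)
}
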