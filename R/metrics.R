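#' NOS strength
#'
#' Node strength of the streamline-count network,
#' \eqn{S_i = \sum_j w_{ij}}: the row sums of the NOS weight matrix.
#'
#' @param c a NOS-weighted [connectome()].
#' @return a `node_metric` vector (named numeric) with attribute
#'   `metric_kind = "nos_strength"`.
#' @export
nos_strength <- function(c) {
  if (inherits(c, "connectome") && c$kind != "nos")
    stop_param("nos_strength expects a NOS-weighted connectome")
  W <- as_weight_matrix(c)
  node_metric(rowSums(W), "nos_strength", rownames(W))
}

#' Scalar-weighted average
#'
#' The streamline-count-weighted mean of the incident scalar (e.g. R1) edge
#' values,
#' \deqn{S_i = \frac{\sum_j w_{ij} v_{ij}}{\sum_j w_{ij}},}
#' where \eqn{w_{ij}} is the number of streamlines and \eqn{v_{ij}} the
#' bundle-median scalar. Unlike a plain strength it is not driven by how
#' many connections a node has, and it is invariant to a global rescaling of
#' the streamline counts. Isolated nodes have no defined value and are
#' returned as `NA` with a warning.
#'
#' @param nos NOS-weighted [connectome()] (provides \eqn{w}).
#' @param scalar scalar-weighted [connectome()] on the same support
#'   (provides \eqn{v}).
#' @return a `node_metric` vector with attribute
#'   `metric_kind = "weighted_average"`; `NA` marks isolated nodes.
#' @export
weighted_average <- function(nos, scalar) {
  check_shared_nodes(nos, scalar)
  if (!identical(edge_support(nos), edge_support(scalar)))
    stop_param("NOS and scalar connectomes must share their edge support")
  w <- nos$weights
  v <- scalar$weights
  denom <- rowSums(w)
  out <- ifelse(denom > 0, rowSums(w * v) / denom, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)),
            " isolated node(s) have no weighted average (NA)")
  node_metric(out, "weighted_average", nos$nodes)
}

node_metric <- function(values, kind, nodes = NULL) {
  v <- as.numeric(values)
  if (!is.null(nodes)) names(v) <- nodes
  attr(v, "metric_kind") <- kind
  class(v) <- c("node_metric", "numeric")
  v
}

#' @export
print.node_metric <- function(x, ...) {
  cat(sprintf("<node_metric> %s, %d nodes\n", attr(x, "metric_kind"),
              length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Standard-deviation hub criterion
#'
#' Hubs are the nodes whose metric value is at least `k_sd` sample standard
#' deviations above the mean (2 by default; 3 is the conservative variant).
#' When the metric is constant (SD = 0) no node exceeds the others and the
#' hub set is empty. `NA` values are excluded from both the threshold and
#' the result.
#'
#' @param m a `node_metric` (or plain numeric vector).
#' @param k_sd number of standard deviations above the mean.
#' @return character vector of hub node names (indices if unnamed).
#' @export
detect_hubs <- function(m, k_sd = 2) {
  v <- as.numeric(m)
  names(v) <- names(m)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop_param("need at least 2 defined values")
  s <- stats::sd(v)
  if (s == 0) return(character(0))
  hubs <- v >= mean(v) + k_sd * s
  if (is.null(names(v))) as.character(which(hubs)) else names(v)[hubs]
}
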