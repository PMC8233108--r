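#' Weighted connectome container
#'
#' A connectome is a symmetric, zero-diagonal edge-weight matrix over an
#' ordered node list, tagged with the kind of weight it carries: `"nos"`
#' (number of streamlines, non-negative integers) or `"scalar"` (bundle-median
#' scalar values, e.g. R1 in 1/s). A zero entry means the edge is absent.
#'
#' @param weights symmetric numeric matrix with zero diagonal.
#' @param kind `"nos"` or `"scalar"`.
#' @param nodes optional character vector of node ids; defaults to the
#'   matrix dimnames or `"n1" ... "nN"`.
#' @param provenance optional list recording how the matrix was built.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, kind = c("nos", "scalar"), nodes = NULL,
                       provenance = list()) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop_param("weight matrix must be square")
  if (any(!is.finite(weights))) stop_param("weights must be finite")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9) {
    idx <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
    stop_param(sprintf(
      "weight matrix is asymmetric beyond 1e-9 (max deviation %.3g at [%d, %d])",
      asym, idx[1], idx[2]))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0)) stop_param("weights must be non-negative")
  # per-subject NOS entries are counts; consensus NOS medians may be
  # half-integers and are exempted
  if (kind == "nos" && !isTRUE(provenance$consensus) &&
      max(abs(weights - round(weights))) > 1e-9)
    stop_param("NOS weights must be integers")
  if (is.null(nodes)) nodes <- rownames(weights)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  if (length(nodes) != n) stop_param("node list length must match matrix size")
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = as.character(nodes), weights = weights, kind = kind,
                 provenance = provenance),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$nodes)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<connectome> %s-weighted, %d nodes, %d edges (density %.3f)\n",
              x$kind, n, ne, ne / (n * (n - 1) / 2)))
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  w <- object$weights[upper.tri(object$weights)]
  w <- w[w != 0]
  out <- list(kind = object$kind, n_nodes = length(object$nodes),
              n_edges = length(w),
              weight_range = if (length(w)) range(w) else c(NA_real_, NA_real_),
              weight_median = if (length(w)) stats::median(w) else NA_real_)
  class(out) <- "summary.connectome"
  out
}

#' @export
print.summary.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s-weighted: %d nodes, %d edges\n",
              x$kind, x$n_nodes, x$n_edges))
  if (x$n_edges > 0)
    cat(sprintf("  weights: median %.4g, range [%.4g, %.4g]\n",
                x$weight_median, x$weight_range[1], x$weight_range[2]))
  invisible(x)
}

# Internal: check two connectomes share a node list.
check_shared_nodes <- function(a, b) {
  if (!identical(a$nodes, b$nodes))
    stop_param("connectomes must share the same node list and ordering")
}

#' Edge support of a connectome
#'
#' @param x a `connectome`.
#' @return logical matrix, `TRUE` where an edge is present (nonzero weight).
#' @export
edge_support <- function(x) {
  s <- x$weights != 0
  diag(s) <- FALSE
  s
}
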