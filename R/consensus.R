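#' Group-consensus edge mask
#'
#' An edge is kept when it is present (nonzero) in at least
#' `ceiling(prevalence * n_subjects)` subjects — the usual 50%-prevalence
#' group-consensus rule at the default.
#'
#' @param c a [cohort()].
#' @param prevalence required fraction of subjects, in (0, 1].
#' @param which `"nos"` or `"scalar"` (the supports coincide for cohorts
#'   built by this package, so the choice is usually immaterial).
#' @return logical node x node matrix.
#' @export
consensus_mask <- function(c, prevalence = 0.5, which = "nos") {
  if (!length(c$subjects)) stop_param("cohort is empty")
  if (prevalence <= 0 || prevalence > 1)
    stop_param("prevalence must lie in (0, 1]")
  counts <- Reduce(`+`, lapply(c$subjects,
                               function(s) edge_support(s[[which]])))
  thr <- ceiling(prevalence * length(c$subjects))
  counts >= thr
}

#' Group-consensus connectomes
#'
#' For every edge in the mask, the consensus weight is the median of the
#' edge's weights across the subjects in which the edge is present (absent
#' subjects are excluded, so a consensus weight never falls below every
#' observed weight; set `include_absent = TRUE` to take the median over all
#' subjects including zeros). Edges outside the mask are 0.
#'
#' @param c a [cohort()].
#' @param mask logical edge mask from [consensus_mask()]; computed at the
#'   default 0.5 prevalence when missing.
#' @param include_absent include zero (absent) weights in the median.
#' @return list with consensus `nos` and `scalar` [connectome()]s.
#' @export
consensus_weights <- function(c, mask = NULL, include_absent = FALSE) {
  if (!length(c$subjects)) stop_param("cohort is empty")
  if (is.null(mask)) mask <- consensus_mask(c)
  n <- length(c$nodes)
  out <- list()
  for (kind in c("nos", "scalar")) {
    stack <- vapply(c$subjects, function(s) s[[kind]]$weights,
                    matrix(0, n, n))
    w <- matrix(0, n, n, dimnames = list(c$nodes, c$nodes))
    idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      vals <- stack[idx[r, 1], idx[r, 2], ]
      if (!include_absent) vals <- vals[vals != 0]
      if (!length(vals)) next
      med <- stats::median(vals)
      w[idx[r, 1], idx[r, 2]] <- med
      w[idx[r, 2], idx[r, 1]] <- med
    }
    out[[kind]] <- connectome(w, kind, c$nodes,
                              provenance = list(consensus = TRUE,
                                                include_absent = include_absent))
  }
  out
}

#' Edge-weight linear regression between two connectomes
#'
#' Ordinary least squares of `a`'s edge weights on `b`'s, over the
#' upper-triangle edges present (nonzero) in both networks. Reports the
#' slope, intercept, R-squared, the two-sided p-value for the slope, and the
#' number of edges used. R-squared is symmetric in the two networks; slope
#' and intercept are not.
#'
#' @param a,b [connectome()]s over the same nodes.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n_edges`.
#' @export
edge_regression <- function(a, b) {
  check_shared_nodes(a, b)
  ut <- upper.tri(a$weights)
  keep <- ut & a$weights != 0 & b$weights != 0
  y <- a$weights[keep]
  x <- b$weights[keep]
  if (length(y) < 3) stop_param("need at least 3 common edges")
  if (stats::var(x) == 0)
    stop_param("predictor weights have zero variance")
  if (stats::var(y) == 0) # constant response: nothing to explain
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                n_edges = length(y)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n_edges = length(y))
}
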