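#' Generate a synthetic cohort of paired NOS/scalar connectomes
#'
#' Draws a population edge template once, then per subject applies edge
#' dropout, truncated-Poisson streamline counts, and class-structured scalar
#' weights, as described in [phantom_spec()]. NOS and scalar matrices of a
#' subject share the same support by construction. Identical `(spec, seed)`
#' reproduce bit-identical cohorts.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return an object of class `cohort`: a list with `subjects` (each a list
#'   with `nos` and `scalar` [connectome()]s), `nodes`, `planted` (the
#'   planted partition), `classes` (the class map), `template` (logical
#'   template edge matrix) and `spec`.
#' @export
generate_cohort_matrices <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_regions
  nodes <- spec$class_map$node
  pairs <- upper_pairs(n)
  same_mod <- spec$planted_partition[pairs[, 1]] ==
    spec$planted_partition[pairs[, 2]]
  p_edge <- ifelse(same_mod, spec$edge_prob_within, spec$edge_prob_between)
  lambda0 <- ifelse(same_mod, spec$lambda_within, spec$lambda_between)
  eff <- spec$scalar_class_effect[spec$class_map$functional]
  v_planted <- spec$scalar_base + (eff[pairs[, 1]] + eff[pairs[, 2]]) / 2

  with_seed(seed, {
    template <- stats::runif(nrow(pairs)) < p_edge
    subjects <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      keep <- template & (stats::runif(nrow(pairs)) < spec$subject_keep)
      nos_e <- integer(nrow(pairs))
      v_e <- numeric(nrow(pairs))
      idx <- which(keep)
      if (length(idx)) {
        sn <- spec$subject_noise_sd
        lam <- lambda0[idx]
        if (sn > 0) # mean-preserving log-normal rate fluctuation
          lam <- lam * exp(stats::rnorm(length(idx), 0, sn) - sn^2 / 2)
        nos_e[idx] <- rpois_trunc1(lam)
        v <- v_planted[idx]
        if (spec$scalar_noise_sd > 0)
          v <- v + stats::rnorm(length(idx), 0, spec$scalar_noise_sd)
        v_e[idx] <- pmin(pmax(v, 1e-6), 3 - 1e-6)
      }
      subjects[[s]] <- list(
        nos = connectome(pairs_to_matrix(nos_e, pairs, n, nodes), "nos"),
        scalar = connectome(pairs_to_matrix(v_e, pairs, n, nodes), "scalar"))
    }
    template_m <- pairs_to_matrix(as.numeric(template), pairs, n, nodes) > 0
    structure(list(subjects = subjects, nodes = nodes,
                   planted = spec$planted_partition,
                   classes = spec$class_map,
                   template = template_m,
                   planted_scalar = pairs_to_matrix(v_planted, pairs, n, nodes),
                   spec = spec, seed = as.integer(seed)),
              class = "cohort")
  })
}

# Poisson truncated to >= 1, vectorized over lambda (inverse-CDF on the
# conditional distribution; degenerate lambda ~ 0 yields 1).
rpois_trunc1 <- function(lambda) {
  lambda <- pmax(lambda, 1e-12)
  p0 <- stats::ppois(0, lambda)
  u <- p0 + stats::runif(length(lambda)) * (1 - p0)
  pmax(1L, stats::qpois(u, lambda))
}

pairs_to_matrix <- function(vals, pairs, n, nodes) {
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  m[pairs] <- vals
  m[pairs[, c(2, 1)]] <- vals
  m
}

#' Assemble a cohort from existing connectome pairs
#'
#' @param subjects list of lists with elements `nos` and `scalar`, each a
#'   [connectome()]; all subjects must share the node ordering, and each
#'   subject's two matrices must share their edge support.
#' @param classes optional class map (`node`, `functional`, `cyto`).
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, classes = NULL) {
  if (!length(subjects)) stop_param("cohort is empty")
  nodes <- subjects[[1]]$nos$nodes
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    if (!inherits(sub$nos, "connectome") || !inherits(sub$scalar, "connectome"))
      stop_param("each subject needs a 'nos' and a 'scalar' connectome")
    if (!identical(sub$nos$nodes, nodes) || !identical(sub$scalar$nodes, nodes))
      stop_param("subject ", s, " does not share the cohort node ordering")
    if (!identical(edge_support(sub$nos), edge_support(sub$scalar)))
      stop_param("subject ", s, ": NOS and scalar supports differ")
  }
  structure(list(subjects = subjects, nodes = nodes, classes = classes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  dens <- mean(vapply(x$subjects, function(s) {
    w <- s$nos$weights
    mean(w[upper.tri(w)] != 0)
  }, numeric(1)))
  cat(sprintf("<cohort> %d subjects, %d nodes, mean edge density %.3f\n",
              length(x$subjects), length(x$nodes), dens))
  if (!is.null(x$planted))
    cat(sprintf("  planted modules: %d\n", max(x$planted)))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subjects)
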