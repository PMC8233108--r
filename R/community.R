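#' Resolution-scaled modularity of a partition
#'
#' Computes
#' \deqn{Q(\gamma) = \frac{1}{2m} \sum_{ij} \left(A_{ij} -
#'   \gamma \frac{k_i k_j}{2m}\right) \delta(c_i, c_j)}
#' with \eqn{k_i = \sum_j A_{ij}}, \eqn{2m = \sum_{ij} A_{ij}}: the weighted
#' configuration (Newman-Girvan) null with the conventional \eqn{1/2m}
#' normalization, scaled by the resolution parameter \eqn{\gamma}. At
#' \eqn{\gamma = 1} a single community always scores exactly 0.
#'
#' @param A a `connectome` or a symmetric non-negative matrix.
#' @param partition a `partition` object or an assignment vector.
#' @param gamma resolution parameter (> 0 for the usual interpretation;
#'   \eqn{\gamma < 1} favours larger modules, \eqn{\gamma > 1} smaller ones).
#' @return the modularity value Q.
#' @export
modularity_score <- function(A, partition, gamma = 1) {
  W <- as_weight_matrix(A)
  ci <- as_assignment(partition, nrow(W))
  two_m <- sum(W)
  if (two_m <= 0) stop_param("graph has no edges (total weight is zero)")
  k <- rowSums(W)
  B <- W - gamma * outer(k, k) / two_m
  same <- outer(ci, ci, "==")
  sum(B[same]) / two_m
}

as_weight_matrix <- function(A) {
  if (inherits(A, "connectome")) A <- A$weights
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_param("matrix must be square")
  if (any(A < 0)) stop_param("weights must be non-negative")
  A
}

as_assignment <- function(p, n) {
  ci <- if (inherits(p, "partition")) p$assignment else p
  ci <- as.integer(ci)
  if (length(ci) != n) stop_param("partition must assign every node")
  if (anyNA(ci)) stop_param("partition must assign every node")
  ci
}

# Renumber labels contiguously from 1 in order of first appearance.
canonical_labels <- function(ci) {
  as.integer(factor(ci, levels = unique(ci)))
}

#' Construct a partition object
#'
#' @param assignment integer module labels, one per node (relabelled to be
#'   contiguous from 1 in order of first appearance).
#' @param q modularity value at `gamma` (optional).
#' @param gamma resolution at which the partition was obtained.
#' @param nodes optional node ids.
#' @return an object of class `partition`.
#' @export
partition <- function(assignment, q = NA_real_, gamma = NA_real_,
                      nodes = NULL) {
  a <- canonical_labels(assignment)
  if (!is.null(nodes)) names(a) <- nodes
  structure(list(assignment = a, q = q, gamma = gamma),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d modules", length(x$assignment),
              max(x$assignment)))
  if (!is.na(x$gamma)) cat(sprintf(", gamma = %g", x$gamma))
  if (!is.na(x$q)) cat(sprintf(", Q = %.4f", x$q))
  cat("\n")
  invisible(x)
}

#' Number of modules in a partition
#' @param p a `partition`.
#' @return integer module count.
#' @export
n_modules <- function(p) max(as_assignment(p, length(p$assignment)))

#' One seeded Louvain run
#'
#' Standard two-phase Louvain heuristic: greedy single-node moves to the
#' neighbouring module with the best Q(gamma) gain, then aggregation of
#' modules into super-nodes, repeated until no move improves Q. The node
#' visiting order is shuffled by `seed`; the run is deterministic given
#' `(A, gamma, seed)` and does not touch R's global RNG.
#'
#' @inheritParams modularity_score
#' @param seed integer seed for the node-visiting order.
#' @return a `partition` with its Q value at `gamma`.
#' @export
louvain_once <- function(A, gamma = 1, seed = 1L) {
  W <- as_weight_matrix(A)
  ci <- louvain_cpp(W, gamma, as.integer(seed))
  partition(ci, q = modularity_score(W, ci, gamma), gamma = gamma,
            nodes = rownames(W))
}

#' Rand pair-counting coefficient of two partitions
#'
#' Fraction of node pairs on which the two partitions agree (both co-assign
#' or both separate the pair).
#'
#' @param p1,p2 partitions (or assignment vectors) over the same nodes.
#' @return the Rand coefficient in `[0, 1]`.
#' @export
rand_index <- function(p1, p2) {
  a <- partition_vec(p1)
  b <- partition_vec(p2)
  if (length(a) != length(b)) stop_param("partitions must cover the same nodes")
  n <- length(a)
  if (n < 2) stop_param("need at least 2 nodes")
  tab <- table(a, b)
  M <- n * (n - 1) / 2
  sumsq <- sum(tab^2)
  M1 <- (sum(rowSums(tab)^2) - n) / 2
  M2 <- (sum(colSums(tab)^2) - n) / 2
  w <- (sumsq - n) / 2
  (M + 2 * w - M1 - M2) / M
}

partition_vec <- function(p) {
  if (inherits(p, "partition")) p$assignment else as.integer(p)
}

#' z-scored Rand coefficient (Traud et al.)
#'
#' Pair-counting similarity of two partitions, z-scored against the
#' hypergeometric null that fixes both partitions' module sizes and permutes
#' node identities. Symmetric in its arguments. Degenerate comparisons whose
#' null variance vanishes (e.g. both partitions a single community) return 0.
#'
#' @inheritParams rand_index
#' @return the z-Rand score.
#' @export
zrand <- function(p1, p2) {
  a <- partition_vec(p1)
  b <- partition_vec(p2)
  if (length(a) != length(b)) stop_param("partitions must cover the same nodes")
  if (length(a) < 2) stop_param("need at least 2 nodes")
  zrand_cpp(as.integer(a), as.integer(b))
}

#' Multi-resolution Louvain sweep
#'
#' Runs Louvain `n_runs` times at each resolution in `gammas` (run seeds
#' derived from `seed`), recording the mean Q and the partition stability,
#' defined as the mean pairwise z-Rand over run pairs (all pairs when
#' `n_runs <= 150`, otherwise a fixed random subsample of up to
#' `max_pairs` pairs). The resolution is then selected by `select_gamma()`
#' and a consensus partition is built from the runs at the selected
#' resolution.
#'
#' @inheritParams modularity_score
#' @param gammas increasing grid of resolutions (default 0.5 to 3 by 0.1,
#'   i.e. 26 levels).
#' @param n_runs Louvain runs per resolution (>= 2).
#' @param seed master seed; every run and the pair subsample derive from it.
#' @param max_pairs cap on the number of run pairs scored per resolution.
#' @param selection `"stability"` (default) picks the gamma with maximal mean
#'   pairwise z-Rand; `"max_q"` picks the gamma with maximal mean Q.
#' @param consensus if `TRUE` (default) compute the consensus partition at
#'   the selected resolution.
#' @return an object of class `sweep_result` with elements `gammas`,
#'   `mean_q`, `stability`, `n_modules` (median module count per gamma),
#'   `partitions` (list of node x run matrices), `selected_gamma`,
#'   `selected_q`, and `consensus` (a `partition` or `NULL`).
#' @export
gamma_sweep <- function(A, gammas = seq(0.5, 3, by = 0.1), n_runs = 1000,
                        seed = 1L, max_pairs = 10000,
                        selection = c("stability", "max_q"),
                        consensus = TRUE) {
  selection <- match.arg(selection)
  W <- as_weight_matrix(A)
  if (n_runs < 2) stop_param("n_runs must be at least 2")
  if (is.unsorted(gammas, strictly = TRUE))
    stop_param("gammas must be strictly increasing")
  ng <- length(gammas)
  n <- nrow(W)
  parts <- vector("list", ng)
  mean_q <- stability <- nmod <- numeric(ng)
  for (g in seq_len(ng)) {
    P <- matrix(0L, n, n_runs)
    qs <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      p <- louvain_once(W, gammas[g], seed = derive_seed(seed, 1L, g, r))
      P[, r] <- p$assignment
      qs[r] <- p$q
    }
    mean_q[g] <- mean(qs)
    nmod[g] <- stats::median(apply(P, 2, max))
    all_pairs <- utils::combn(n_runs, 2)
    if (ncol(all_pairs) > max_pairs) {
      keep <- with_seed(derive_seed(seed, 2L, g),
                        sample.int(ncol(all_pairs), max_pairs))
      all_pairs <- all_pairs[, keep, drop = FALSE]
    }
    stability[g] <- mean_pairwise_zrand_cpp(P, t(all_pairs) - 1L)
    parts[[g]] <- P
  }
  res <- structure(list(gammas = gammas, mean_q = mean_q,
                        stability = stability, n_modules = nmod,
                        partitions = parts, selection = selection,
                        n_runs = n_runs, seed = seed,
                        nodes = rownames(W)),
                   class = "sweep_result")
  res$selected_gamma <- select_gamma(res)
  gi <- match(res$selected_gamma, gammas)
  res$selected_q <- mean_q[gi]
  if (consensus) {
    cp <- consensus_partition(parts[[gi]], seed = derive_seed(seed, 3L, gi))
    cp$gamma <- gammas[gi]
    cp$q <- modularity_score(W, cp$assignment, gammas[gi])
    if (!is.null(rownames(W))) names(cp$assignment) <- rownames(W)
    res$consensus <- cp
  }
  res
}

#' Select the resolution parameter from a sweep
#'
#' By default picks the gamma whose runs are most mutually stable (maximal
#' mean pairwise z-Rand); ties break toward the smaller gamma. With
#' `selection = "max_q"` picks the gamma with the largest mean Q instead
#' (note Q at small gamma systematically exceeds Q at large gamma, so this
#' reading is rarely useful across a wide grid).
#'
#' @param s a `sweep_result`.
#' @param selection override the selection rule stored in the sweep.
#' @return the selected gamma value.
#' @export
select_gamma <- function(s, selection = NULL) {
  if (is.null(selection)) selection <- s$selection
  crit <- if (selection == "max_q") s$mean_q else s$stability
  s$gammas[which.max(crit)] # which.max returns the first (smallest) maximum
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d resolutions in [%g, %g], %d runs each\n",
              length(x$gammas), min(x$gammas), max(x$gammas), x$n_runs))
  cat(sprintf("  selected gamma = %g (%s), mean Q = %.4f\n",
              x$selected_gamma, x$selection, x$selected_q))
  if (!is.null(x$consensus))
    cat(sprintf("  consensus partition: %d modules\n",
                n_modules(x$consensus)))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$gammas, x$stability, type = "b", pch = 16,
                 xlab = expression(gamma), ylab = "mean pairwise z-Rand",
                 main = "partition stability", ...)
  graphics::abline(v = x$selected_gamma, lty = 2)
  graphics::plot(x$gammas, x$mean_q, type = "b", pch = 16,
                 xlab = expression(gamma), ylab = "mean Q",
                 main = "modularity", ...)
  graphics::abline(v = x$selected_gamma, lty = 2)
  invisible(x)
}

#' Consensus partition from an ensemble of partitions
#'
#' Builds the module co-assignment (agreement) matrix of the ensemble,
#' zeroes entries at or below the chance level estimated by independently
#' permuting each partition's labels across nodes (`n_null` permutations),
#' and reruns Louvain (gamma = 1) on the thresholded agreement matrix until
#' all runs agree, iterating the agreement-threshold-cluster cycle if
#' needed (Lancichinetti-Fortunato style consensus clustering).
#'
#' @param partitions a list of `partition` objects / assignment vectors over
#'   the same nodes, or a node x run integer matrix.
#' @param seed integer seed (permutation null and Louvain reruns).
#' @param n_null number of label permutations for the chance level.
#' @param n_runs Louvain runs per consensus iteration.
#' @param max_iter maximum agreement-recluster iterations.
#' @return a `partition` (its `q` slot holds the modularity of the final
#'   partition on the last thresholded agreement matrix at gamma = 1).
#' @export
consensus_partition <- function(partitions, seed = 1L, n_null = 100,
                                n_runs = 100, max_iter = 100) {
  P <- partitions_matrix(partitions)
  if (ncol(P) < 2) stop_param("need at least 2 partitions")
  n <- nrow(P)
  for (iter in seq_len(max_iter)) {
    D <- agreement_cpp(P)
    thr <- null_agreement_level(P, derive_seed(seed, 11L, iter), n_null)
    Dt <- D
    Dt[Dt <= thr] <- 0
    if (all(Dt == 0)) {
      # no above-chance agreement: every node is its own module
      return(partition(seq_len(n), q = 0, gamma = 1))
    }
    runs <- matrix(0L, n, n_runs)
    for (r in seq_len(n_runs)) {
      runs[, r] <- louvain_cpp(Dt, 1, derive_seed(seed, 12L, iter, r))
    }
    runs <- apply(runs, 2, canonical_labels)
    if (all(runs == runs[, 1])) {
      ci <- runs[, 1]
      return(partition(ci, q = modularity_score(Dt, ci, 1), gamma = 1))
    }
    P <- runs
  }
  stop_param(sprintf(
    "consensus did not converge in %d iterations (last ensemble had %d-%d modules)",
    max_iter, min(apply(P, 2, max)), max(apply(P, 2, max))))
}

partitions_matrix <- function(partitions) {
  if (is.matrix(partitions)) return(apply(partitions, 2, canonical_labels))
  if (!is.list(partitions)) stop_param("give a list of partitions or a matrix")
  vecs <- lapply(partitions, partition_vec)
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1)
    stop_param("all partitions must cover the same nodes")
  matrix(unlist(lapply(vecs, canonical_labels)), nrow = lens[1])
}

# Mean off-diagonal agreement among label-permuted copies of the ensemble:
# the chance co-assignment level implied by the module size distributions.
null_agreement_level <- function(P, seed, n_null) {
  n <- nrow(P)
  with_seed(seed, {
    acc <- 0
    for (b in seq_len(n_null)) {
      Pp <- apply(P, 2, function(col) col[sample.int(n)])
      Dp <- agreement_cpp(Pp)
      acc <- acc + mean(Dp[upper.tri(Dp)])
    }
    acc / n_null
  })
}
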