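# Independent oracles used across tests: exhaustive set-partition search for
# maximal modularity, and a permutation Monte-Carlo reference for the z-Rand
# statistic. These deliberately avoid the package's own optimized paths.

# All set partitions of n elements as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  recurse <- function(i, maxl) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible(NULL))
    }
    for (l in seq_len(maxl + 1)) {
      a[i] <<- l
      recurse(i + 1, max(maxl, l))
    }
  }
  recurse(1, 0)
  out
}

# Exhaustive maximal Q over all partitions (feasible for n <= 8).
brute_force_q_max <- function(A, gamma = 1) {
  n <- nrow(A)
  two_m <- sum(A)
  k <- rowSums(A)
  B <- A - gamma * outer(k, k) / two_m
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- sum(B[outer(p, p, "==")]) / two_m
    if (q > best) best <- q
  }
  best
}

# Monte-Carlo z-score of the co-co-assignment pair count under random
# permutations of one partition's labels (the hypergeometric null).
zrand_perm_oracle <- function(p1, p2, n_perm = 4000) {
  w_stat <- function(a, b) {
    tab <- table(a, b)
    sum(tab * (tab - 1) / 2)
  }
  obs <- w_stat(p1, p2)
  sims <- replicate(n_perm, w_stat(p1, sample(p2)))
  (obs - mean(sims)) / sd(sims)
}

# Symmetric random weighted graph with planted sparsity.
random_weighted_graph <- function(n, p_edge = 0.6) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on_ <- up[runif(length(up)) < p_edge]
  A[on_] <- round(runif(length(on_), 0.5, 5), 2)
  A <- A + t(A)
  # ensure the graph has at least one edge
  if (sum(A) == 0) {
    A[1, 2] <- A[2, 1] <- 1
  }
  A
}
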