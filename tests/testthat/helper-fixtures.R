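# Small constructed fixtures shared by the test files.

toy_connectome <- function(m, kind = "nos", nodes = NULL) {
  connectome(m, kind, nodes)
}

# A 4-subject cohort over 4 nodes with hand-written weights, used for the
# exact consensus checks. Edge (1,2) is present in subjects 2 and 3 only.
hand_cohort <- function() {
  nodes <- paste0("n", 1:4)
  mk <- function(w12, w13, w34, v12, v13, v34) {
    nos <- matrix(0, 4, 4)
    scl <- matrix(0, 4, 4)
    nos[1, 2] <- nos[2, 1] <- w12
    nos[1, 3] <- nos[3, 1] <- w13
    nos[3, 4] <- nos[4, 3] <- w34
    scl[1, 2] <- scl[2, 1] <- v12
    scl[1, 3] <- scl[3, 1] <- v13
    scl[3, 4] <- scl[4, 3] <- v34
    list(nos = connectome(nos, "nos", nodes),
         scalar = connectome(scl, "scalar", nodes))
  }
  cohort(list(mk(0, 2, 2, 0, 1.10, 1.05),
              mk(3, 4, 100, 1.20, 1.15, 1.30),
              mk(5, 6, 4, 1.10, 1.05, 1.10),
              mk(0, 8, 0, 0, 1.25, 0)))
}

# Two disconnected unit-weight triangles.
two_triangles <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

# Two disconnected k-cliques with unit weights.
two_cliques <- function(k) {
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- 1
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  A
}

tempfile_with <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}

# Small planted-partition spec used in several downstream tests.
small_planted_spec <- function(...) {
  phantom_spec(n_regions = 60, n_subjects = 35, n_modules = 4,
               lambda_within = 20, lambda_between = 2,
               edge_prob_within = 0.9, edge_prob_between = 0.1, ...)
}
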