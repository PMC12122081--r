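# Independent oracles and small fixture builders used across the suite.

# Brute-force LP oracle for balanced transport via boot::simplex (a generic
# simplex implementation, independent of the package's network simplex).
# One of the m + n equality constraints is redundant and dropped.
lp_oracle <- function(a, b, C) {
  m <- length(a); n <- length(b)
  A3 <- matrix(0, m + n, m * n)
  for (i in seq_len(m))
    for (j in seq_len(n)) {
      A3[i, (j - 1) * m + i] <- 1
      A3[m + j, (j - 1) * m + i] <- 1
    }
  s <- boot::simplex(a = as.vector(C), A3 = A3[-(m + n), , drop = FALSE],
                     b3 = c(a, b)[-(m + n)], maxi = FALSE)
  s$value
}

# Monte-Carlo estimate of P(hit j before returning to i | start at i),
# simulating all walks in lock-step.
mc_hitting_prob <- function(P, i, j, n_walks = 1e5, max_steps = 10000L) {
  E <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  state <- rep.int(i, n_walks)
  alive <- rep.int(TRUE, n_walks)
  hit <- logical(n_walks)
  for (s in seq_len(max_steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    r <- runif(length(idx))
    nxt <- rowSums(r > cum[state[idx], , drop = FALSE]) + 1L
    state[idx] <- nxt
    hit[idx[nxt == j]] <- TRUE
    alive[idx[nxt == j | nxt == i]] <- FALSE
  }
  mean(hit)
}

# Random strictly positive row-stochastic matrix (irreducible, aperiodic).
random_chain <- function(E) {
  P <- matrix(runif(E * E, min = 0.05, max = 1), E, E)
  P / rowSums(P)
}

# Block-structured distance matrix: tight within-block, far between.
block_D <- function(sizes, within = 0.1, between = 10) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(between, n, n)
  for (g in seq_along(sizes)) D[lab == g, lab == g] <- within
  diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  D
}

# Tiny two-group cohort (smaller and faster than the study-scale default).
small_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_spec(n_cell_types = 5L, samples_per_group = 4L,
                              density = 0.8, seed = seed, ...))
}

# Edge table data frame for parser tests.
edge_table_df <- function() {
  data.frame(sample = c("s1", "s1", "s2"),
             source = c("A", "B", "A"),
             target = c("B", "A", "B"),
             weight = c(1, 2, 3),
             stringsAsFactors = FALSE)
}
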