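#' Stationary distribution of an irreducible Markov chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for the unique invariant distribution of
#' an irreducible row-stochastic matrix.  Uses a direct linear solve for
#' chains up to `direct_max` states and power iteration above; the result is
#' validated against the fixed-point residual.
#'
#' @param P Row-stochastic matrix (or an `otccc_transition`); irreducibility
#'   is guaranteed upstream by any positive teleportation weight.
#' @param direct_max Largest dimension solved by dense factorization.
#' @param tol Fixed-point residual tolerance (`max |pi P - pi|`).
#' @return Numeric vector `pi` (positive, sums to 1), named like `P`'s rows.
#' @export
stationary_distribution <- function(P, direct_max = 2000L, tol = 1e-8) {
  P <- .as_transition_matrix(P)
  E <- nrow(P)
  if (E <= direct_max) {
    A <- t(P) - diag(E)
    A[E, ] <- 1                       # replace one redundant equation
    pi <- solve(A, c(rep(0, E - 1L), 1))
  } else {
    pi <- rep(1 / E, E)
    for (it in seq_len(100000L)) {
      nxt <- as.vector(pi %*% P)
      if (max(abs(nxt - pi)) < tol / 10) { pi <- nxt; break }
      pi <- nxt
    }
  }
  pi <- pi / sum(pi)
  res <- max(abs(as.vector(pi %*% P) - pi))
  if (res > tol)
    stop("stationary distribution did not converge (residual ",
         format(res), ")")
  names(pi) <- rownames(P)
  pi
}

#' Hitting probabilities before return
#'
#' For an irreducible chain, `Q[i, j]` is the probability that a walk started
#' at `i` reaches `j` before returning to `i`.  Starting from `i`, the number
#' of visits to `i` before absorption at `j` is geometric with success
#' probability `Q[i, j]`, so `Q[i, j] = 1 / N_ii` where
#' `N = (I - P[-j, -j])^{-1}` is the fundamental matrix of the chain with `j`
#' absorbing.  One dense solve per target column serves all sources.
#'
#' @param P Row-stochastic irreducible matrix (or `otccc_transition`).
#' @return Matrix `Q` with off-diagonal entries in `(0, 1]`; the diagonal is
#'   set to 1 (the return probability of a recurrent state) and is never
#'   consumed downstream.
#' @export
hitting_probabilities <- function(P) {
  P <- .as_transition_matrix(P)
  E <- nrow(P)
  Q <- matrix(1, E, E, dimnames = dimnames(P))
  if (E == 1L) return(Q)
  I1 <- diag(E - 1L)
  for (j in seq_len(E)) {
    M <- I1 - P[-j, -j, drop = FALSE]
    N <- tryCatch(solve(M), error = function(e)
      stop("absorbing-chain system is singular for state ", j,
           " (is the chain irreducible?)"))
    d <- diag(N)                      # expected visits to i before hitting j
    if (any(d < 1 - 1e-9))
      stop("invalid fundamental matrix for state ", j)
    Q[-j, j] <- 1 / d
  }
  Q
}

#' Hitting-time-distance ground cost over STG vertices
#'
#' From the stationary distribution `pi` and hitting probabilities `Q` of the
#' regularized STG chain, forms the normalized hitting-time matrix `T` and
#' the cost `C = -log T` used as the optimal-transport ground metric between
#' directed cell-pair interactions.
#'
#' Two normalization variants are provided because the scaling of the second
#' factor is ambiguous in the hitting-time-metric literature:
#' * `"as_printed"`: `T_ij = sqrt(pi_i) * sqrt(pi_j) * Q_ij` — the literal
#'   product form; off-diagonal costs are then at least `log 2`.
#' * `"similarity"`: `T_ij = sqrt(pi_i / pi_j) * Q_ij` — the
#'   similarity-transform convention, which yields an exactly symmetric cost
#'   because `pi_i Q_ij = pi_j Q_ji` (the stationary probability flux between
#'   two states is the same in both directions).
#' In both variants `T_ii = 1` so the diagonal cost is exactly 0.  With
#' `symmetrize = TRUE` (default) the cost is averaged with its transpose so
#' downstream sample-to-sample distances are symmetric under either variant.
#'
#' @param P Row-stochastic irreducible matrix (or `otccc_transition`).
#' @param variant `"as_printed"` (default) or `"similarity"`.
#' @param symmetrize Average `C` with its transpose (default `TRUE`).
#' @return Cost matrix with zero diagonal and attributes `variant` and
#'   `symmetrized`.
#' @export
htd_cost <- function(P, variant = c("as_printed", "similarity"),
                     symmetrize = TRUE) {
  variant <- match.arg(variant)
  P <- .as_transition_matrix(P)
  pi <- stationary_distribution(P)
  Q <- hitting_probabilities(P)
  s <- sqrt(pi)
  Tm <- switch(variant,
               as_printed = outer(s, s) * Q,
               similarity = outer(s, 1 / s) * Q)
  diag(Tm) <- 1
  if (any(Tm <= 0)) stop("normalized hitting-time matrix has entries <= 0")
  C <- -log(Tm)
  if (symmetrize) C <- (C + t(C)) / 2
  diag(C) <- 0
  dimnames(C) <- dimnames(P)
  attr(C, "variant") <- variant
  attr(C, "symmetrized") <- symmetrize
  C
}

#' Write a ground-cost matrix as square CSV indexed by edge labels
#'
#' @param C Cost matrix from [htd_cost()] or [corr_cost()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(C, path) write_distance_matrix(C, path)
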