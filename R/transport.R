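#' Normalize a non-negative signal to the probability simplex
#'
#' Balanced optimal transport assumes mass conservation, so each sample's
#' edge signal is rescaled to total mass 1 before transport.
#'
#' @param weights Non-negative numeric vector with positive sum.
#' @param sample_id Optional id used in the error message.
#' @return `weights / sum(weights)`.
#' @export
normalize_signal <- function(weights, sample_id = NULL) {
  if (any(weights < 0) || anyNA(weights))
    stop("signal must be non-negative",
         if (!is.null(sample_id)) paste0(" (sample '", sample_id, "')"))
  s <- sum(weights)
  if (s <= 0)
    stop("signal has zero total mass",
         if (!is.null(sample_id)) paste0(" (sample '", sample_id, "')"))
  weights / s
}

# Exact balanced OT on the strictly positive atoms; re-embeds the plan on
# the full support.  q is rescaled to sum(p) to absorb rounding.
.ot_exact <- function(p, q, C, plan = FALSE) {
  ip <- which(p > 0); iq <- which(q > 0)
  a <- p[ip]; b <- q[iq]
  b <- b * (sum(a) / sum(b))
  if (length(ip) == 1L || length(iq) == 1L) {
    G <- outer(a, b) / sum(a)
    cost <- sum(G * C[ip, iq, drop = FALSE])
    res <- list(cost = cost, plan = G, converged = TRUE)
  } else {
    res <- ot_lp_cpp(a, b, C[ip, iq, drop = FALSE])
    if (!res$converged) stop("transportation simplex did not converge")
  }
  if (!plan) return(res$cost)
  G <- matrix(0, length(p), length(q), dimnames = list(names(p), names(q)))
  G[ip, iq] <- res$plan
  list(cost = res$cost, plan = G)
}

# Log-domain Sinkhorn on strictly positive atoms; stable down to small
# epsilon.  Returns <gamma, C> and the dual-feasible plan.
.ot_sinkhorn <- function(p, q, C, epsilon, max_iter = 20000L, tol = 1e-9) {
  ip <- which(p > 0); iq <- which(q > 0)
  a <- p[ip]; b <- q[iq]; b <- b / sum(b); a <- a / sum(a)
  Cs <- C[ip, iq, drop = FALSE]
  la <- log(a); lb <- log(b)
  f <- numeric(length(a)); g <- numeric(length(b))
  lse <- function(M) {                 # row-wise log-sum-exp
    mx <- apply(M, 1L, max)
    mx + log(rowSums(exp(M - mx)))
  }
  Mc <- -Cs / epsilon
  err <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f <- epsilon * (la - lse(sweep(Mc, 2L, g / epsilon, `+`)))
    g <- epsilon * (lb - lse(t(Mc + f / epsilon)))
    if (it %% 10L == 0L || it == max_iter) {
      lG <- Mc + outer(f, g, `+`) / epsilon
      err <- max(abs(rowSums(exp(lG)) - a))
      if (err < tol) break
    }
  }
  if (!(err < tol * 10))
    stop("Sinkhorn did not converge after ", it, " iterations (marginal ",
         "error ", format(err), ")")
  Gs <- exp(Mc + outer(f, g, `+`) / epsilon)
  G <- matrix(0, length(p), length(q), dimnames = list(names(p), names(q)))
  G[ip, iq] <- Gs
  list(cost = sum(Gs * Cs), plan = G, iterations = it)
}

.default_epsilon <- function(C) {
  m <- max(C)
  if (m <= 0) 1e-2 else 1e-2 * m
}

#' Wasserstein distance between two edge signals
#'
#' Solves the balanced optimal-transport problem between two probability
#' vectors supported on the STG vertices under a ground cost `C`:
#' the minimum of `<Gamma, C>` over couplings with marginals `p` and `q`.
#' `"exact_lp"` (default) solves the transportation linear program with a
#' network-simplex and is exact and deterministic; `"sinkhorn"` returns the
#' entropically regularized transport cost `<Gamma_eps, C>`, which decreases
#' to the exact value as `epsilon` shrinks.
#'
#' @param p,q Probability vectors of equal length `E` (see
#'   [normalize_signal()]).
#' @param C `E x E` non-negative cost matrix with zero diagonal.
#' @param method `"exact_lp"` or `"sinkhorn"`.
#' @param epsilon Entropic regularization; default 1% of `max(C)`.
#' @param max_iter,tol Sinkhorn iteration controls.
#' @return List with `distance`, `plan` (an `E x E` coupling), and `method`.
#' @examples
#' C <- matrix(c(0, 1, 1, 0), 2)
#' wasserstein(c(0.7, 0.3), c(0.3, 0.7), C)$distance  # 0.4
#' @export
wasserstein <- function(p, q, C, method = c("exact_lp", "sinkhorn"),
                        epsilon = NULL, max_iter = 20000L, tol = 1e-9) {
  method <- match.arg(method)
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length")
  if (length(p) != nrow(C) || nrow(C) != ncol(C))
    stop("cost matrix dimensions must match the signals")
  if (any(C < 0)) stop("ground cost must be non-negative")
  p <- normalize_signal(p); q <- normalize_signal(q)
  names(p) <- rownames(C); names(q) <- colnames(C)
  if (method == "exact_lp") {
    res <- .ot_exact(p, q, C, plan = TRUE)
  } else {
    if (is.null(epsilon)) epsilon <- .default_epsilon(C)
    res <- .ot_sinkhorn(p, q, C, epsilon, max_iter = max_iter, tol = tol)
  }
  list(distance = res$cost, plan = res$plan, method = method)
}

#' Pairwise Wasserstein distance matrix between samples
#'
#' Normalizes each row of the edge-signal matrix to a probability vector and
#' computes all pairwise transport distances under the ground cost `C`.
#' When `C` is symmetric only unordered pairs are solved.
#'
#' @param signal_matrix Samples-by-edges matrix from
#'   [build_edge_signal_matrix()]; every row must have positive sum.
#' @param C Ground cost over edges (columns of `signal_matrix`).
#' @param method `"exact_lp"` (default) or `"sinkhorn"`.
#' @param epsilon Sinkhorn regularization (see [wasserstein()]).
#' @param tag Method tag stored on the result, e.g. `"dwot"` for the
#'   hitting-time ground metric or `"corr_ot"` for the correlation baseline.
#' @return Square distance matrix with sample ids as dimnames, zero
#'   diagonal, and attribute `method`.
#' @export
pairwise_distances <- function(signal_matrix, C,
                               method = c("exact_lp", "sinkhorn"),
                               epsilon = NULL, tag = "dwot") {
  method <- match.arg(method)
  stopifnot(is.matrix(signal_matrix), ncol(signal_matrix) == nrow(C))
  n <- nrow(signal_matrix)
  Pn <- t(apply(signal_matrix, 1L, normalize_signal))
  sym <- isTRUE(all.equal(C, t(C), tolerance = 1e-12,
                          check.attributes = FALSE))
  D <- matrix(0, n, n,
              dimnames = list(rownames(signal_matrix),
                              rownames(signal_matrix)))
  dist_fun <- function(p, q) {
    if (method == "exact_lp") .ot_exact(p, q, C)
    else .ot_sinkhorn(p, q, C,
                      if (is.null(epsilon)) .default_epsilon(C)
                      else epsilon)$cost
  }
  for (k in seq_len(n - 1L))
    for (l in seq((k + 1L), n)) {
      D[k, l] <- dist_fun(Pn[k, ], Pn[l, ])
      D[l, k] <- if (sym) D[k, l] else dist_fun(Pn[l, ], Pn[k, ])
    }
  attr(D, "method") <- tag
  D
}

#' Unbalanced Wasserstein distance with KL marginal relaxation
#'
#' Entropically regularized unbalanced optimal transport: the hard marginal
#' constraints of the balanced problem are replaced by Kullback-Leibler
#' penalties of strength `rho`, so the two signals need not carry the same
#' total mass.  The reported value is
#' `<Gamma, C> + rho KL(Gamma 1 | p) + rho KL(Gamma' 1 | q)`.  As
#' `rho -> Inf` with normalized inputs the value approaches the balanced
#' Sinkhorn cost at the same `epsilon`.
#'
#' @param p,q Non-negative vectors (not necessarily normalized).
#' @param C Ground cost matrix.
#' @param rho Marginal-relaxation strength (> 0), default 1.
#' @param epsilon Entropic regularization; default 1% of `max(C)`.
#' @param max_iter,tol Scaling-iteration controls.
#' @return List with `distance`, `plan`, `transport_cost` (the `<Gamma, C>`
#'   part) and `penalty`.
#' @export
unbalanced_wasserstein <- function(p, q, C, rho = 1, epsilon = NULL,
                                   max_iter = 20000L, tol = 1e-10) {
  if (length(p) != length(q)) stop("'p' and 'q' must have the same length")
  if (any(p < 0) || any(q < 0)) stop("signals must be non-negative")
  if (rho <= 0) stop("'rho' must be positive")
  if (is.null(epsilon)) epsilon <- .default_epsilon(C)
  K <- exp(-C / epsilon)
  fi <- rho / (rho + epsilon)
  u <- rep(1, length(p)); v <- rep(1, length(q))
  pow <- function(x) ifelse(x > 0, x^fi, 0)
  for (it in seq_len(max_iter)) {
    Kv <- as.vector(K %*% v)
    u_new <- pow(ifelse(Kv > 0, p / Kv, 0))
    Ku <- as.vector(crossprod(K, u_new))
    v_new <- pow(ifelse(Ku > 0, q / Ku, 0))
    delta <- max(abs(u_new - u), abs(v_new - v))
    u <- u_new; v <- v_new
    if (delta < tol) break
  }
  G <- u * K * rep(v, each = length(u))
  dimnames(G) <- dimnames(C)
  kl <- function(x, y) {
    pos <- x > 0
    if (any(pos & y <= 0)) return(Inf)
    sum(x[pos] * log(x[pos] / y[pos])) - sum(x) + sum(y)
  }
  tc <- sum(G * C)
  pen <- rho * (kl(rowSums(G), p) + kl(colSums(G), q))
  list(distance = tc + pen, plan = G, transport_cost = tc, penalty = pen)
}

#' Correlation-distance ground cost (CORR-OT baseline)
#'
#' Baseline ground cost over STG vertices that ignores graph topology:
#' `C[i, j] = 1 - cor(signal_matrix[, i], signal_matrix[, j])` (Pearson,
#' across samples).  Columns with zero variance have undefined correlation;
#' by convention their correlation is taken as 0, i.e. distance 1 to every
#' other column.  The diagonal is forced to 0.
#'
#' @param signal_matrix Samples-by-edges matrix with at least two rows.
#' @return Edge-by-edge cost matrix.
#' @export
corr_cost <- function(signal_matrix) {
  stopifnot(is.matrix(signal_matrix))
  if (nrow(signal_matrix) < 2L)
    stop("correlation cost needs at least two samples")
  cc <- suppressWarnings(cor(signal_matrix))
  cc[is.na(cc)] <- 0
  C <- 1 - cc
  diag(C) <- 0
  C
}
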