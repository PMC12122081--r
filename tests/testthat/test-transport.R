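test_that("signals normalize to the simplex", {
  expect_equal(normalize_signal(c(2, 2)), c(0.5, 0.5))
  p <- c(0.1, 0.6, 0.3)
  expect_equal(normalize_signal(p), p)          # idempotent on the simplex
  set.seed(1)
  w <- runif(10)
  expect_equal(sum(normalize_signal(w)), 1)
  expect_equal(normalize_signal(w) * sum(w), w)
  expect_error(normalize_signal(rep(0, 3), sample_id = "s9"), "s9")
  expect_error(normalize_signal(c(-1, 2)), "non-negative")
})

test_that("exact transport solves canonical instances", {
  C <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(wasserstein(c(0.5, 0.5), c(0.5, 0.5), C)$distance, 0)
  res <- wasserstein(c(1, 0), c(0, 1), C)
  expect_equal(res$distance, 1)
  expect_equal(res$plan[1, 2], 1)
  expect_equal(wasserstein(c(0.7, 0.3), c(0.3, 0.7), C)$distance, 0.4)
  expect_error(wasserstein(c(1, 0), c(0, 0.5, 0.5), C), "length")
})

test_that("exact LP equals the brute-force oracle and conserves marginals", {
  skip_if_not_installed("boot")
  set.seed(21)
  for (t in 1:25) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    a <- normalize_signal(runif(m)); b <- normalize_signal(runif(n))
    C <- matrix(runif(m * n), m, n)
    r <- otccc:::ot_lp_cpp(a, b, C)
    expect_lt(abs(r$cost - lp_oracle(a, b, C)), 1e-9)
    expect_lt(max(abs(rowSums(r$plan) - a)), 1e-7)
    expect_lt(max(abs(colSums(r$plan) - b)), 1e-7)
    expect_lt(abs(sum(r$plan) - 1), 1e-7)
  }
})

test_that("Sinkhorn value decreases to the exact LP value as epsilon shrinks", {
  set.seed(22)
  E <- 5
  p <- normalize_signal(runif(E)); q <- normalize_signal(runif(E))
  C <- matrix(runif(E * E), E, E); C <- (C + t(C)) / 2; diag(C) <- 0
  exact <- wasserstein(p, q, C)$distance
  errs <- vapply(c(0.5, 0.1, 0.02, 0.004), function(eps)
    wasserstein(p, q, C, method = "sinkhorn", epsilon = eps)$distance - exact,
    0)
  expect_true(all(diff(abs(errs)) < 1e-9))   # monotone approach
  expect_lt(abs(errs[4]), 5e-3)
  # regularized transport cost stays above the LP optimum (minus slack)
  expect_true(all(errs > -1e-8))
})

test_that("pairwise distance matrices behave like distances", {
  sim <- small_cohort(seed = 13L)
  S <- build_edge_signal_matrix(sim$cohort)
  C <- htd_cost(regularized_transition(build_stg(sim$cohort), 0.05))
  D <- pairwise_distances(S, C)
  expect_equal(diag(D), rep(0, nrow(D)), ignore_attr = TRUE)
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(D >= 0))

  # identical rows give zero distance
  S2 <- rbind(a = S[1, ], b = S[1, ])
  expect_equal(max(pairwise_distances(S2, C)), 0)

  # permuting samples permutes the matrix identically
  perm <- sample(nrow(S))
  Dp <- pairwise_distances(S[perm, ], C)
  expect_equal(Dp, D[perm, perm], ignore_attr = TRUE)
})

test_that("unbalanced transport relaxes toward the balanced problem", {
  set.seed(23)
  E <- 4
  C <- matrix(runif(E * E, 0.5, 1), E, E); diag(C) <- 0
  p <- normalize_signal(runif(E))

  # identical marginals: value is (near) zero at the default regularization
  expect_lt(unbalanced_wasserstein(p, p, C, rho = 1)$distance, 0.05)

  # large rho with normalized inputs matches the balanced Sinkhorn value
  q <- normalize_signal(runif(E))
  eps <- 0.01
  bal <- wasserstein(p, q, C, method = "sinkhorn", epsilon = eps)$distance
  unb <- unbalanced_wasserstein(p, q, C, rho = 1e3, epsilon = eps)$distance
  expect_lt(abs(unb - bal) / bal, 0.01)

  # pure mass creation (q = 2p): cost grows with the penalty strength rho
  vals <- vapply(c(0.1, 1, 10), function(rho)
    unbalanced_wasserstein(p, 2 * p, C, rho = rho)$distance, 0)
  expect_true(all(diff(vals) > 0))
  expect_error(unbalanced_wasserstein(p, q, C, rho = 0), "rho")
})

test_that("correlation-distance baseline matches the Pearson formula", {
  set.seed(24)
  M <- matrix(runif(40), 8, 5)
  M <- cbind(M, dup = M[, 1], anti = max(M[, 1]) + min(M[, 1]) - M[, 1])
  C <- corr_cost(M)
  expect_equal(C[1, 6], 0)            # duplicated column
  expect_equal(C[1, 7], 2)            # anti-correlated column
  expect_equal(diag(C), rep(0, 7), ignore_attr = TRUE)
  for (i in 2:5) for (j in 2:5)
    if (i != j) expect_equal(C[i, j], 1 - cor(M[, i], M[, j]))

  # zero-variance convention: distance 1 to everything, 0 on the diagonal
  Mz <- cbind(M[, 1:3], flat = rep(1, 8))
  Cz <- corr_cost(Mz)
  expect_equal(Cz[4, 1:3], rep(1, 3), ignore_attr = TRUE)
  expect_equal(Cz[4, 4], 0)
  expect_error(corr_cost(M[1, , drop = FALSE]), "two samples")
})
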