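test_that("k-medoids recovers block structure found by exhaustive search", {
  D <- block_D(c(2, 2))
  fit <- k_medoids(D, 2)
  expect_equal(adjusted_rand_index(fit$labels, c(1, 1, 2, 2)), 1)

  # exhaustive search over all 2-partitions of the 4 points
  best <- Inf
  for (mask in 1:7) {
    part <- as.integer(intToBits(mask))[1:4] + 1L
    if (length(unique(part)) < 2) next
    loss <- 0
    for (g in 1:2) {
      members <- which(part == g)
      loss <- loss + min(colSums(D[members, members, drop = FALSE]))
    }
    best <- min(best, loss / 4)
  }
  expect_equal(fit$loss, best)

  # k = n: every point its own medoid, loss 0
  expect_equal(k_medoids(D, 4)$loss, 0)
  # k = 1: medoid minimizes the distance row sums
  fit1 <- k_medoids(D, 1)
  expect_equal(fit1$representatives, which.min(rowSums(D)))
  expect_error(k_medoids(D, 5), "between 1")
  expect_error(k_medoids(D[, 1:3], 2), "square")
})

test_that("Sinkhorn barycenters satisfy fixed-point and symmetry properties", {
  set.seed(31)
  E <- 6
  C <- matrix(runif(E * E, 0.5, 1), E, E); C <- (C + t(C)) / 2; diag(C) <- 0
  v <- normalize_signal(runif(E))

  # identical members: the barycenter reproduces them up to entropic blur
  mu <- sinkhorn_barycenter(rbind(v, v, v), C = C, epsilon = 0.005)
  expect_lt(sum(abs(mu - v)), 0.02)
  expect_equal(sum(mu), 1, tolerance = 1e-9)

  # degenerate weights select one member
  w2 <- normalize_signal(runif(E))
  mu1 <- sinkhorn_barycenter(rbind(v, w2), member_weights = c(1, 0), C = C,
                             epsilon = 0.005)
  expect_lt(sum(abs(mu1 - v)), 0.02)

  # swapping two support points that the cost treats symmetrically
  # permutes the barycenter the same way
  Cs <- matrix(1, 3, 3); diag(Cs) <- 0
  a <- c(0.6, 0.3, 0.1); b <- c(0.1, 0.3, 0.6)
  mu2 <- sinkhorn_barycenter(rbind(a, b), C = Cs, epsilon = 0.01)
  expect_equal(mu2[1], mu2[3], tolerance = 1e-6)
})

test_that("seeding spreads initial barycenters across separated groups", {
  D <- block_D(c(4, 4))
  S <- matrix(runif(8 * 3) + 0.1, 8, 3)  # signals unused in farthest mode
  picks <- seed_barycenters(S, C = NULL, k = 2, seed = 1, D = D)
  expect_length(unique(picks), 2L)
  expect_true(xor(picks[1] <= 4, picks[2] <= 4))  # one pick per block
  expect_length(seed_barycenters(S, C = NULL, k = 1, seed = 3, D = D), 1L)
  picks5 <- seed_barycenters(S, C = NULL, k = 5, seed = 2, D = D,
                             mode = "sampling")
  expect_length(unique(picks5), 5L)
})

test_that("k-barycenters EM is monotone, deterministic, and recovers groups", {
  sim <- small_cohort(seed = 17L)
  S <- build_edge_signal_matrix(sim$cohort)
  C <- htd_cost(regularized_transition(build_stg(sim$cohort), 0.05))
  fit <- k_barycenters(S, C, 2, n_restarts = 3, seed = 5)
  expect_equal(adjusted_rand_index(fit$labels, sim$true_labels), 1)
  for (tr in fit$restart_traces)
    expect_true(all(diff(tr) <= 1e-9))
  expect_equal(fit$loss, min(fit$restart_losses))
  expect_equal(rowSums(fit$representatives), rep(1, 2), tolerance = 1e-6,
               ignore_attr = TRUE)

  # bitwise determinism under the same seed
  fit2 <- k_barycenters(S, C, 2, n_restarts = 3, seed = 5)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$representatives, fit2$representatives)
  expect_identical(fit$loss, fit2$loss)

  # k = 1 degenerates to a single barycenter of all samples
  fit1 <- k_barycenters(S, C, 1, n_restarts = 1, seed = 1)
  expect_true(all(fit1$labels == 1L))
  mu_all <- sinkhorn_barycenter(t(apply(S, 1, normalize_signal)), C = C)
  expect_equal(unname(fit1$representatives[1, ]), unname(as.vector(mu_all)),
               tolerance = 1e-4)
})

test_that("silhouette separates tight blocks and flags random labels", {
  D <- block_D(c(5, 5))
  sil <- silhouette_score(D, rep(1:2, each = 5))
  expect_gt(sil$mean, 0.9)

  # homogeneous distances with arbitrary labels score near zero
  set.seed(33)
  n <- 20
  Dh <- matrix(1, n, n); diag(Dh) <- 0
  expect_lt(abs(silhouette_score(Dh, sample(1:2, n, TRUE))$mean), 0.05)

  # singleton clusters take width 0 by convention
  s3 <- silhouette_score(D, c(1, rep(2, 4), rep(3, 5)))
  expect_equal(s3$widths[1], 0)
  expect_error(silhouette_score(D, rep(1, 10)), "two clusters")
})
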