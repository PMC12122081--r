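#' @rdname k_medoids
#' @export
print.otccc_clustering <- function(x, ...) {
  cat("<otccc_clustering>", x$method, "- k =", length(unique(x$labels)),
      ", n =", length(x$labels), ", mean loss =", format(x$loss), "\n")
  invisible(x)
}

.new_clustering <- function(labels, representatives, loss, cluster_loss,
                            method, seed, ...) {
  structure(list(labels = labels, representatives = representatives,
                 loss = loss, cluster_loss = cluster_loss,
                 method = method, seed = seed, ...),
            class = "otccc_clustering")
}

.check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'D' must be a square matrix")
  if (max(abs(diag(D))) > 1e-10) stop("'D' must have a zero diagonal")
  if (max(abs(D - t(D))) > 1e-8) stop("'D' must be symmetric")
  invisible(D)
}

#' k-medoids clustering on a precomputed distance matrix
#'
#' PAM-style partitioning around medoids: deterministic greedy BUILD
#' initialization (first medoid minimizes total distance; each further
#' medoid maximally decreases the assignment cost), then alternation of
#' (i) assigning every sample to its nearest medoid and (ii) moving each
#' medoid to the in-cluster sample minimizing the summed within-cluster
#' distance, until the labels stabilize.  All ties break to the lowest
#' index, so the result is fully reproducible.
#'
#' @param D Square symmetric distance matrix with zero diagonal, e.g. from
#'   [pairwise_distances()].
#' @param k Number of clusters, `1 <= k <= nrow(D)`.
#' @param seed Recorded for provenance; the algorithm is deterministic.
#' @param max_iter Cap on assign/update sweeps.
#' @return An `otccc_clustering`: `labels` (1..k), `representatives` (medoid
#'   row indices), `loss` (mean distance to assigned medoid) and
#'   `cluster_loss` (per-cluster means).
#' @export
k_medoids <- function(D, k, seed = 1L, max_iter = 100L) {
  .check_distance_matrix(D)
  n <- nrow(D)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of samples")
  # BUILD
  med <- which.min(rowSums(D))
  while (length(med) < k) {
    dmin <- apply(D[, med, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(cand) {
      if (cand %in% med) return(-Inf)
      sum(pmax(dmin - D[, cand], 0))
    }, 0)
    med <- c(med, which.max(gain))
  }
  assign_to <- function(med) {
    dm <- D[, med, drop = FALSE]
    max.col(-dm, ties.method = "first")
  }
  labels <- assign_to(med)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (!length(members)) next
      within <- colSums(D[members, members, drop = FALSE])
      med[j] <- members[which.min(within)]
    }
    new_labels <- assign_to(med)
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  d_assigned <- D[cbind(seq_len(n), med[labels])]
  cl <- vapply(seq_len(k), function(j) {
    m <- labels == j
    if (any(m)) mean(d_assigned[m]) else NA_real_
  }, 0)
  .new_clustering(labels, med, mean(d_assigned), cl, "k_medoids",
                  as.integer(seed))
}

#' Fixed-support entropic Wasserstein barycenter
#'
#' Computes the weighted Sinkhorn barycenter of a set of probability vectors
#' supported on the STG vertex set via iterative Bregman projections
#' (simultaneous Sinkhorn scalings against a shared kernel
#' `K = exp(-C / epsilon)`, with a weighted geometric mean coupling step).
#' The support is the full vertex set, so the barycenter is itself a signal
#' over directed cell-pair edges and can be rendered as a representative
#' CCC graph.
#'
#' @param signals Matrix with one signal per row (or a list of vectors);
#'   rows are normalized to probability vectors.
#' @param member_weights Barycentric weights, default uniform; normalized to
#'   sum 1.
#' @param C Ground cost over the support.
#' @param epsilon Entropic regularization; default 1% of `max(C)`.
#' @param tol L1 convergence tolerance on successive barycenter iterates.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named probability vector over the support, with attributes
#'   `iterations` and `residual`.
#' @export
sinkhorn_barycenter <- function(signals, member_weights = NULL, C,
                                epsilon = NULL, tol = 1e-6,
                                max_iter = 10000L) {
  if (is.list(signals)) signals <- do.call(rbind, signals)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  stopifnot(ncol(signals) == nrow(C), nrow(C) == ncol(C))
  p <- nrow(signals); E <- ncol(signals)
  if (is.null(member_weights)) member_weights <- rep(1 / p, p)
  if (length(member_weights) != p || any(member_weights < 0) ||
      sum(member_weights) <= 0)
    stop("'member_weights' must be non-negative with positive sum")
  w <- member_weights / sum(member_weights)
  if (is.null(epsilon)) epsilon <- .default_epsilon(C)
  B <- apply(signals, 1L, normalize_signal)      # E x p, columns = members
  K <- exp(-C / epsilon)
  U <- matrix(1, E, p)
  mu <- rowMeans(B)
  for (it in seq_len(max_iter)) {
    KtU <- crossprod(K, U)
    V <- B / KtU
    KV <- K %*% V
    log_mu <- as.vector(log(KV) %*% w)
    mu_new <- exp(log_mu)
    mu_new <- mu_new / sum(mu_new)
    U <- mu_new / KV
    res <- sum(abs(mu_new - mu))
    mu <- mu_new
    if (res < tol) {
      names(mu) <- colnames(signals)
      attr(mu, "iterations") <- it
      attr(mu, "residual") <- res
      return(mu)
    }
  }
  stop("Sinkhorn barycenter did not converge after ", max_iter,
       " iterations (residual ", format(res), ")")
}

#' Seed initial barycenters by spreading picks in Wasserstein geometry
#'
#' k-means++-style seeding over the samples: the first representative is
#' drawn uniformly at random; each subsequent one either maximizes
#' (`"farthest"`, default) or is sampled proportionally to
#' (`"sampling"`, squared-distance weights) the distance to the nearest
#' representative already chosen.  Chosen samples' signals become the
#' initial barycenters of the EM algorithm.
#'
#' @param signals Samples-by-edges matrix (rows normalized internally).
#' @param C Ground cost; used to compute distances when `D` is not given.
#' @param k Number of seeds.
#' @param seed RNG seed for the (only) random choice(s).
#' @param mode `"farthest"` or `"sampling"`.
#' @param D Optional precomputed pairwise sample distance matrix.
#' @return Integer vector of `k` distinct sample indices.
#' @export
seed_barycenters <- function(signals, C, k, seed = 1L,
                             mode = c("farthest", "sampling"), D = NULL) {
  mode <- match.arg(mode)
  n <- nrow(signals)
  if (k > n) stop("'k' cannot exceed the number of samples")
  if (is.null(D)) D <- pairwise_distances(signals, C)
  set.seed(as.integer(seed))
  picks <- sample.int(n, 1L)
  while (length(picks) < k) {
    dmin <- apply(D[, picks, drop = FALSE], 1L, min)
    dmin[picks] <- 0
    nxt <- if (mode == "farthest") which.max(dmin)
           else sample.int(n, 1L, prob = dmin^2 + 1e-12)
    if (nxt %in% picks) nxt <- which.max(dmin)   # sampling-mode collision
    picks <- c(picks, nxt)
  }
  picks
}

#' k-barycenters EM clustering of CCC graphs
#'
#' Expectation-maximization in Wasserstein space.  Per restart: pick initial
#' barycenters by [seed_barycenters()]; then alternate an E-step assigning
#' each sample to its nearest barycenter under the exact LP transport
#' distance, and an M-step replacing each cluster's barycenter by the
#' [sinkhorn_barycenter()] of its members.  Because the entropic barycenter
#' optimizes a regularized surrogate, each M-step update is accepted only if
#' it does not increase the cluster's mean exact transport loss, which makes
#' the monitored objective (mean over samples of the distance to the
#' assigned barycenter) non-increasing across iterations.  A restart stops
#' when the labels are unchanged and the barycenters move less than `tol` in
#' L1; across restarts the solution with the lowest mean loss is returned.
#' Clusters that empty out are re-seeded with the sample farthest from its
#' current barycenter.
#'
#' @param signals Samples-by-edges matrix from
#'   [build_edge_signal_matrix()].
#' @param C Ground cost over edges (e.g. [htd_cost()]).
#' @param k Number of clusters.
#' @param n_restarts Independent restarts; 100 by default, smaller values
#'   are appropriate for exploratory runs and tests.
#' @param seed Master RNG seed; restart seeds are derived from it, so equal
#'   seeds reproduce identical results bit for bit.
#' @param epsilon Barycenter regularization (see [sinkhorn_barycenter()]).
#' @param tol L1 barycenter-movement threshold declaring convergence.
#' @param max_iter EM iteration cap per restart.
#' @param seeding Seeding mode passed to [seed_barycenters()].
#' @param D Optional precomputed pairwise distance matrix (reused by the
#'   seeding step across restarts; computed once if missing).
#' @return An `otccc_clustering` with `representatives` a `k x E` matrix of
#'   barycenters, `loss` (mean exact distance to assigned barycenter),
#'   `cluster_loss`, `loss_trace` (per-iteration loss of the winning
#'   restart), `restart_losses`, `restart_traces` and `n_restarts_used`.
#' @export
k_barycenters <- function(signals, C, k, n_restarts = 100L, seed = 1L,
                          epsilon = NULL, tol = 1e-6, max_iter = 200L,
                          seeding = c("farthest", "sampling"), D = NULL) {
  seeding <- match.arg(seeding)
  stopifnot(is.matrix(signals), ncol(signals) == nrow(C))
  n <- nrow(signals)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of samples")
  if (is.null(epsilon)) epsilon <- .default_epsilon(C)
  Pn <- t(apply(signals, 1L, normalize_signal))
  dimnames(Pn) <- dimnames(signals)
  if (is.null(D)) D <- pairwise_distances(Pn, C)
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)

  dist_to <- function(mu) {           # n x k exact LP distances
    vapply(seq_len(nrow(mu)), function(j)
      vapply(seq_len(n), function(i) .ot_exact(Pn[i, ], mu[j, ], C), 0),
      numeric(n))
  }

  run_restart <- function(rs) {
    idx <- seed_barycenters(Pn, C, k, seed = rs, mode = seeding, D = D)
    mu <- Pn[idx, , drop = FALSE]
    labels <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      dmat <- dist_to(mu)
      new_labels <- max.col(-dmat, ties.method = "first")
      # re-seed empty clusters with the worst-served sample
      for (j in which(tabulate(new_labels, k) == 0L)) {
        far <- which.max(dmat[cbind(seq_len(n), new_labels)])
        new_labels[far] <- j
      }
      loss <- mean(dmat[cbind(seq_len(n), new_labels)])
      trace <- c(trace, loss)
      moved <- Inf
      mu_new <- mu
      for (j in seq_len(k)) {
        members <- which(new_labels == j)
        if (!length(members)) next
        cand <- sinkhorn_barycenter(Pn[members, , drop = FALSE], C = C,
                                    epsilon = epsilon)
        cand <- as.vector(cand)
        d_cand <- vapply(members, function(i) .ot_exact(Pn[i, ], cand, C), 0)
        if (mean(d_cand) <= mean(dmat[members, j])) mu_new[j, ] <- cand
      }
      moved <- sum(abs(mu_new - mu))
      converged <- identical(new_labels, labels) && moved < tol
      labels <- new_labels
      mu <- mu_new
      if (converged) break
    }
    dmat <- dist_to(mu)
    final_loss <- mean(dmat[cbind(seq_len(n), labels)])
    list(labels = labels, mu = mu, loss = final_loss,
         trace = c(trace, final_loss), iterations = it)
  }

  runs <- lapply(restart_seeds, run_restart)
  losses <- vapply(runs, `[[`, 0, "loss")
  best <- which.min(losses)
  run <- runs[[best]]
  cl <- vapply(seq_len(k), function(j) {
    m <- run$labels == j
    dj <- vapply(which(m), function(i) .ot_exact(Pn[i, ], run$mu[j, ], C), 0)
    if (length(dj)) mean(dj) else NA_real_
  }, 0)
  rownames(run$mu) <- paste0("barycenter_", seq_len(k))
  .new_clustering(run$labels, run$mu, run$loss, cl, "k_barycenters",
                  as.integer(seed),
                  loss_trace = run$trace,
                  restart_losses = losses,
                  restart_traces = lapply(runs, `[[`, "trace"),
                  n_restarts_used = n_restarts,
                  epsilon = epsilon)
}

#' Mean silhouette of a clustering under a precomputed distance matrix
#'
#' Standard silhouette analysis (via the `cluster` package) used to judge
#' whether a cohort supports more clusters than its known labels; singleton
#' clusters take width 0 by convention.
#'
#' @param D Square symmetric distance matrix with zero diagonal.
#' @param labels Cluster assignment (>= 2 distinct clusters).
#' @return List with `mean` and per-sample `widths`.
#' @export
silhouette_score <- function(D, labels) {
  .check_distance_matrix(D)
  if (length(labels) != nrow(D))
    stop("'labels' length must match 'D'")
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  widths <- sil[, "sil_width"]
  list(mean = mean(widths), widths = widths)
}
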