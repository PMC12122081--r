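#' Build the shared topology graph (directed line graph of the cohort)
#'
#' The shared topology graph (STG) is the directed line graph over the union
#' of directed edges of all samples: each vertex is one directed cell-pair
#' edge `u -> v`, and a line-graph edge runs from vertex `(u, v)` to vertex
#' `(v, w)` whenever the target cell type of the first equals the source cell
#' type of the second (head-to-tail compatibility; a self-loop edge `(A, A)`
#' is compatible with itself).  The line-graph edge weight is the proportion
#' of samples whose graph contains *both* original edges, so transport
#' between commonly co-occurring interactions is cheaper than between rare
#' ones.
#'
#' @param cohort A [ccc_cohort()] with at least one sample and one edge.
#' @return An object of class `otccc_stg`: list with `vertices` (edge labels
#'   in signal-matrix column order), `source`/`target` (the cell types each
#'   vertex connects), `adjacency` (dense co-occurrence-weighted adjacency,
#'   entries in `[0, 1]`) and `n_graphs`.
#' @seealso [regularized_transition()], [build_edge_signal_matrix()]
#' @export
build_stg <- function(cohort) {
  M <- build_edge_signal_matrix(cohort)
  ends <- .split_edge_labels(colnames(M))
  member <- M > 0                                   # samples x edges
  cooc <- crossprod(member) / nrow(member)          # P(both edges present)
  compat <- outer(ends$target, ends$source, `==`)   # head-to-tail rule
  W <- cooc * compat
  dimnames(W) <- list(colnames(M), colnames(M))
  structure(list(vertices = colnames(M),
                 source = ends$source, target = ends$target,
                 adjacency = W, n_graphs = nrow(M)),
            class = "otccc_stg")
}

#' @export
print.otccc_stg <- function(x, ...) {
  cat("<otccc_stg>", length(x$vertices), "vertices (directed cell-pair edges),",
      sum(x$adjacency > 0), "line-graph edges, built from", x$n_graphs,
      "samples\n")
  invisible(x)
}

#' Regularized Markov transition matrix on the STG
#'
#' Row-normalizes the STG adjacency into a transition matrix and mixes it
#' with the uniform distribution, PageRank style:
#' `P = (1 - alpha) * D^{-1} W + alpha / E * J`.  Vertices without outgoing
#' compatible edges (dangling rows) are given a uniform row before mixing.
#' Any `alpha > 0` makes `P` strictly positive, hence irreducible and
#' aperiodic, which the hitting-time machinery requires; the default 0.05 is
#' kept small so the chain is perturbed minimally.
#'
#' @param stg An `otccc_stg` (or a bare non-negative adjacency matrix).
#' @param alpha Teleportation weight in `[0, 1)`.
#' @return Object of class `otccc_transition`: list with the row-stochastic
#'   matrix `P` and `alpha`.
#' @export
regularized_transition <- function(stg, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1)")
  W <- if (inherits(stg, "otccc_stg")) stg$adjacency else as.matrix(stg)
  if (any(W < 0)) stop("adjacency must be non-negative")
  E <- nrow(W)
  rs <- rowSums(W)
  dangling <- rs == 0
  if (any(dangling)) {
    W[dangling, ] <- 1 / E
    rs[dangling] <- 1
  }
  P <- (1 - alpha) * (W / rs) + alpha / E
  structure(list(P = P, alpha = alpha), class = "otccc_transition")
}

#' @export
print.otccc_transition <- function(x, ...) {
  cat("<otccc_transition>", nrow(x$P), "states, alpha =", x$alpha, "\n")
  invisible(x)
}

# Accept either the otccc_transition wrapper or a bare stochastic matrix.
.as_transition_matrix <- function(P) {
  if (inherits(P, "otccc_transition")) P <- P$P
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-8)
    stop("matrix is not row-stochastic")
  P
}

#' Write the STG as an edge list for inspection
#'
#' @param stg An `otccc_stg`.
#' @param path Output CSV path; columns `edge_u`, `edge_v`, `weight`.
#' @return `path`, invisibly.
#' @export
write_stg <- function(stg, path) {
  stopifnot(inherits(stg, "otccc_stg"))
  idx <- which(stg$adjacency > 0, arr.ind = TRUE)
  write.csv(data.frame(edge_u = stg$vertices[idx[, 1L]],
                       edge_v = stg$vertices[idx[, 2L]],
                       weight = stg$adjacency[idx]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
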