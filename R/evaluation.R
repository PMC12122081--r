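.contingency <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have the same length")
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the
#' contingency-table formula: the raw pair-agreement count is centred by its
#' expectation under the permutation model and scaled by the maximum
#' achievable agreement.  Invariant to relabelling of either partition;
#' 1 for identical partitions, about 0 for independent ones, negative for
#' partitions that agree less than chance.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Numeric scalar in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  ct <- .contingency(labels_a, labels_b)
  n <- sum(ct)
  if (n < 2L) return(1)
  ch2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(ch2(ct))
  sum_a <- sum(ch2(rowSums(ct)))
  sum_b <- sum(ch2(colSums(ct)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_nij - expected) / (max_index - expected)
}

#' Rand index
#'
#' Uncorrected fraction of sample pairs on which two partitions agree
#' (placed together in both, or apart in both).
#'
#' @inheritParams adjusted_rand_index
#' @return Numeric scalar in `[0, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  ct <- .contingency(labels_a, labels_b)
  n <- sum(ct)
  if (n < 2L) return(1)
  ch2 <- function(x) x * (x - 1) / 2
  (ch2(n) + 2 * sum(ch2(ct)) - sum(ch2(rowSums(ct))) -
     sum(ch2(colSums(ct)))) / ch2(n)
}

#' Sweep the number of clusters and score recovery of known labels
#'
#' Runs a clustering algorithm for every `k` in a range (and every seed),
#' scoring each partition against the true labels with the adjusted Rand
#' index and the Rand index — the benchmark shape used to compare methods on
#' cohorts with known disease status.  Reports the records plus the argmax-
#' ARI `k` and the ARI at `k` equal to the number of true classes.
#'
#' @param D Pairwise sample distance matrix (required for `k_medoids`, and
#'   reused for seeding by `k_barycenters`).
#' @param true_labels Known class labels, one per sample.
#' @param algorithm `"k_medoids"` or `"k_barycenters"`.
#' @param k_min,k_max Range of cluster numbers (default 2..7).
#' @param seeds Integer vector of seeds; one record per `(k, seed)`.
#' @param signals,C Needed when `algorithm = "k_barycenters"`.
#' @param ... Further arguments for the clustering function (e.g.
#'   `n_restarts`).
#' @return List of class `otccc_sweep`: `records` (data frame with columns
#'   algorithm, k, seed, ari, rand), `k_best`, `ari_max`, `k_true`,
#'   `ari_at_k_true`.
#' @export
sweep_k <- function(D, true_labels, algorithm = c("k_medoids",
                                                  "k_barycenters"),
                    k_min = 2L, k_max = 7L, seeds = 1L,
                    signals = NULL, C = NULL, ...) {
  algorithm <- match.arg(algorithm)
  if (k_min < 1L || k_max < k_min) stop("invalid k range")
  n <- length(true_labels)
  if (k_max > n) stop("'k_max' cannot exceed the number of samples")
  if (algorithm == "k_barycenters" && (is.null(signals) || is.null(C)))
    stop("k_barycenters sweep needs 'signals' and 'C'")
  grid <- expand.grid(k = seq(k_min, k_max), seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    k <- grid$k[r]; s <- grid$seed[r]
    fit <- if (algorithm == "k_medoids") k_medoids(D, k, seed = s)
           else k_barycenters(signals, C, k, seed = s, D = D, ...)
    data.frame(algorithm = algorithm, k = k, seed = s,
               ari = adjusted_rand_index(fit$labels, true_labels),
               rand = rand_index(fit$labels, true_labels))
  })
  records <- do.call(rbind, rows)
  k_true <- length(unique(true_labels))
  by_k <- tapply(records$ari, records$k, mean)
  k_best <- as.integer(names(by_k)[which.max(by_k)])
  ari_at_true <- if (k_true >= k_min && k_true <= k_max)
    mean(records$ari[records$k == k_true]) else NA_real_
  structure(list(records = records, k_best = k_best,
                 ari_max = max(by_k), k_true = k_true,
                 ari_at_k_true = ari_at_true),
            class = "otccc_sweep")
}

#' @export
print.otccc_sweep <- function(x, ...) {
  cat("<otccc_sweep>", nrow(x$records), "runs; best k =", x$k_best,
      "(mean ARI", format(round(x$ari_max, 3)), "); ARI at true k =",
      format(round(x$ari_at_k_true, 3)), "\n")
  invisible(x)
}

#' @rdname cohort-writers
#' @param sweep An `otccc_sweep`.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "otccc_sweep"))
  write.csv(sweep$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
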