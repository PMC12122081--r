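#' Validated configuration for a full pipeline run
#'
#' Collects and validates every tunable of the cohort-to-clusters pipeline
#' before any computation happens; [run_pipeline()] echoes the configuration
#' to a run manifest so a run is fully determined by its manifest.
#'
#' @param input Path to an edge table (file or per-sample directory); may be
#'   `NULL` when `cohort` is given.
#' @param cohort A [ccc_cohort()] used directly instead of reading `input`.
#' @param output_dir Directory for artifacts (created if missing).
#' @param delim Input delimiter, `NULL` to auto-detect.
#' @param labels_file Optional CSV with columns `sample_id`, `label`.
#' @param alpha Teleportation weight for [regularized_transition()].
#' @param variant Hitting-time normalization variant, see [htd_cost()].
#' @param symmetrize Symmetrize the ground cost (default `TRUE`).
#' @param ot `"balanced"` (exact LP distances on the hitting-time cost),
#'   `"corr"` (correlation-distance ground cost), or `"unbalanced"`.
#' @param epsilon Entropic regularization for Sinkhorn steps (`NULL`: 1% of
#'   the maximum ground cost).
#' @param rho Marginal relaxation for unbalanced transport.
#' @param algorithm `"k_medoids"`, `"k_barycenters"`, or `"both"`.
#' @param k Number of clusters.
#' @param k_range Optional `c(k_min, k_max)`; when given, a silhouette/ARI
#'   sweep report is written as well.
#' @param n_restarts Restarts for the k-barycenters EM.
#' @param seed Master seed.
#' @param quiet Suppress progress messages.
#' @return A validated `otccc_config` list.
#' @export
make_run_config <- function(input = NULL, cohort = NULL, output_dir,
                            delim = NULL, labels_file = NULL,
                            alpha = 0.05,
                            variant = c("as_printed", "similarity"),
                            symmetrize = TRUE,
                            ot = c("balanced", "corr", "unbalanced"),
                            epsilon = NULL, rho = 1,
                            algorithm = c("both", "k_medoids",
                                          "k_barycenters"),
                            k = 2L, k_range = NULL, n_restarts = 100L,
                            seed = 1L, quiet = FALSE) {
  variant <- match.arg(variant)
  ot <- match.arg(ot)
  algorithm <- match.arg(algorithm)
  if (is.null(input) && is.null(cohort))
    stop("either 'input' or 'cohort' must be given")
  if (!is.null(cohort) && !inherits(cohort, "ccc_cohort"))
    stop("'cohort' must be a ccc_cohort")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1)")
  if (alpha == 0)
    warning("alpha = 0 does not guarantee an irreducible chain", call. = FALSE)
  if (!is.numeric(k) || k < 1) stop("'k' must be a positive integer")
  if (!is.null(k_range) &&
      (length(k_range) != 2L || k_range[1] < 1 || k_range[2] < k_range[1]))
    stop("'k_range' must be c(k_min, k_max)")
  if (rho <= 0) stop("'rho' must be positive")
  if (n_restarts < 1) stop("'n_restarts' must be >= 1")
  structure(list(input = input, cohort = cohort, output_dir = output_dir,
                 delim = delim, labels_file = labels_file, alpha = alpha,
                 variant = variant, symmetrize = symmetrize, ot = ot,
                 epsilon = epsilon, rho = rho, algorithm = algorithm,
                 k = as.integer(k), k_range = k_range,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "otccc_config")
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the cohort-to-clusters pipeline
#'
#' Reads (or accepts) a cohort, builds the shared topology graph and its
#' regularized Markov chain, derives the hitting-time ground cost, computes
#' the pairwise sample distance matrix, clusters the samples, and writes all
#' artifacts: `distance_matrix.csv`, per-algorithm `labels_*.csv`,
#' `medoids.csv` / `barycenter_*.csv`, transport maps between cluster
#' representatives, optional `sweep_*.csv` and `silhouette.csv` reports, and
#' `run_manifest.txt` echoing every parameter and seed.
#'
#' @param config An `otccc_config` from [make_run_config()].
#' @return Invisibly, a list with the computed objects (`cohort`, `signals`,
#'   `cost`, `distances`, `fits`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "otccc_config"))
  q <- config$quiet
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, paste0(...))
  paths <- character(0)

  labels <- NULL
  if (!is.null(config$labels_file)) {
    lt <- .read_delim_table(config$labels_file, config$delim)
    .check_columns(lt, c("sample_id", "label"), "labels file")
    labels <- stats::setNames(lt$label, lt$sample_id)
  }
  cohort <- .stage("cohort_io", q, {
    if (!is.null(config$cohort)) config$cohort
    else read_edge_table(config$input, delim = config$delim, labels = labels)
  })
  if (is.null(labels)) labels <- cohort$labels

  signals <- .stage("cohort_io", q, build_edge_signal_matrix(cohort))

  C <- .stage("ground_cost", q, {
    if (config$ot == "corr") {
      corr_cost(signals)
    } else {
      stg <- build_stg(cohort)
      P <- regularized_transition(stg, alpha = config$alpha)
      htd_cost(P, variant = config$variant,
               symmetrize = config$symmetrize)
    }
  })

  D <- .stage("transport", q, {
    if (config$ot == "unbalanced") {
      Pn <- t(apply(signals, 1L, normalize_signal))
      n <- nrow(Pn)
      Du <- matrix(0, n, n, dimnames = list(rownames(signals),
                                            rownames(signals)))
      for (i in seq_len(n - 1L))
        for (j in seq((i + 1L), n)) {
          d <- unbalanced_wasserstein(Pn[i, ], Pn[j, ], C,
                                      rho = config$rho,
                                      epsilon = config$epsilon)$distance
          Du[i, j] <- Du[j, i] <- d
        }
      attr(Du, "method") <- "dwot_unbalanced"
      Du
    } else {
      pairwise_distances(signals, C,
                         tag = if (config$ot == "corr") "corr_ot"
                               else "dwot")
    }
  })
  paths <- c(paths, write_distance_matrix(D, out("distance_matrix.csv")))

  algorithms <- if (config$algorithm == "both")
    c("k_medoids", "k_barycenters") else config$algorithm
  fits <- list()
  for (alg in algorithms) {
    fit <- .stage(alg, q, {
      if (alg == "k_medoids") k_medoids(D, config$k, seed = config$seed)
      else k_barycenters(signals, C, config$k,
                         n_restarts = config$n_restarts,
                         seed = config$seed, epsilon = config$epsilon,
                         D = D)
    })
    fits[[alg]] <- fit
    lab <- stats::setNames(fit$labels, rownames(signals))
    paths <- c(paths, write_labels(lab, out("labels_", alg, ".csv")))
    if (alg == "k_medoids") {
      med <- data.frame(cluster = seq_along(fit$representatives),
                        sample_id = rownames(signals)[fit$representatives])
      write.csv(med, out("medoids.csv"), row.names = FALSE, quote = FALSE)
      paths <- c(paths, out("medoids.csv"))
      reps <- t(apply(signals[fit$representatives, , drop = FALSE], 1L,
                      normalize_signal))
    } else {
      reps <- fit$representatives
      for (j in seq_len(nrow(reps)))
        paths <- c(paths, write_signal_edges(
          stats::setNames(reps[j, ], colnames(signals)),
          out("barycenter_", alg, "_", j, ".csv")))
    }
    # transport maps between cluster representatives (interpretation layer)
    if (nrow(reps) >= 2L && config$ot != "unbalanced")
      for (a in seq_len(nrow(reps) - 1L))
        for (b in seq((a + 1L), nrow(reps))) {
          wp <- wasserstein(reps[a, ], reps[b, ], C)
          dimnames(wp$plan) <- list(colnames(signals), colnames(signals))
          paths <- c(paths, write_transport_plan(
            wp$plan, out("transport_map_", alg, "_", a, "_", b, ".csv")))
        }
  }

  if (!is.null(config$k_range)) {
    rep_rows <- list()
    for (alg in algorithms) {
      sil <- vapply(seq(config$k_range[1], config$k_range[2]), function(kk) {
        if (kk < 2L) return(NA_real_)
        f <- if (alg == "k_medoids") k_medoids(D, kk, seed = config$seed)
             else k_barycenters(signals, C, kk,
                                n_restarts = config$n_restarts,
                                seed = config$seed, D = D)
        silhouette_score(D, f$labels)$mean
      }, 0)
      rep_rows[[alg]] <- data.frame(algorithm = alg,
                                    k = seq(config$k_range[1],
                                            config$k_range[2]),
                                    mean_silhouette = sil)
      if (!is.null(labels)) {
        sw <- sweep_k(D, labels, algorithm = alg,
                      k_min = max(2L, config$k_range[1]),
                      k_max = config$k_range[2],
                      seeds = config$seed, signals = signals, C = C,
                      n_restarts = config$n_restarts)
        paths <- c(paths, write_sweep(sw, out("sweep_", alg, ".csv")))
      }
    }
    write.csv(do.call(rbind, rep_rows), out("silhouette.csv"),
              row.names = FALSE, quote = FALSE)
    paths <- c(paths, out("silhouette.csv"))
  }

  manifest <- c(
    paste0("package_version = ", as.character(utils::packageVersion("otccc"))),
    paste0("n_samples = ", nrow(signals)),
    paste0("n_edges = ", ncol(signals)),
    vapply(setdiff(names(config), "cohort"), function(nm)
      paste0(nm, " = ", paste(format(config[[nm]]), collapse = ",")), ""))
  writeLines(manifest, out("run_manifest.txt"))
  paths <- c(paths, out("run_manifest.txt"))
  if (!q) message("wrote ", length(paths), " artifact(s) to ",
                  config$output_dir)
  invisible(list(cohort = cohort, signals = signals, cost = C,
                 distances = D, fits = fits, paths = paths))
}
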