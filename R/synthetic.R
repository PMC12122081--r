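#' Specification for a synthetic CCC cohort
#'
#' Describes a cohort of directed weighted cell-cell communication graphs
#' with known group structure, mimicking what ligand-receptor analysis of a
#' patient cohort produces: a shared directed edge set over a fixed set of
#' cell types (self-loops allowed), positive right-skewed edge weights, and
#' group-specific communication programs.  Each group is assigned a distinct
#' "hub" cell type and the edges incident to that hub (and to no other
#' group's hub, so the affected edge blocks are disjoint) have their mean
#' weight multiplied by `effect_size` — emulating a disease-linked cell type
#' whose incoming/outgoing communication is amplified.  Per-sample
#' variability is multiplicative lognormal jitter plus independent edge
#' dropout.
#'
#' Defaults model a pancreatic-adenocarcinoma-sized cohort: 10 cell types at
#' edge density 0.75 give about 75 directed interactions per sample, two
#' groups of 10 samples, a 5-fold hub effect and 10% lognormal jitter.
#'
#' @param n_cell_types Number of cell types (graph nodes).
#' @param n_groups Number of sample groups (each gets one hub cell type).
#' @param samples_per_group Samples per group.
#' @param density Probability that each of the `n_cell_types^2` possible
#'   directed edges (self-loops included) is in the shared edge set.
#' @param effect_size Multiplicative group effect on hub-incident edges
#'   (>= 1; 1 means no group signal).
#' @param sigma Lognormal jitter (sdlog) applied per sample and edge.
#' @param dropout Probability that an edge is missing from a sample.
#' @param base_sdlog Spread of the shared per-edge baseline mean weights.
#' @param seed RNG seed fixing the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cell_types = 10L, n_groups = 2L,
                        samples_per_group = 10L, density = 0.75,
                        effect_size = 5, sigma = 0.1, dropout = 0,
                        base_sdlog = 0.5, seed = 1L) {
  stopifnot(n_cell_types >= 2L, n_groups >= 1L, n_groups <= n_cell_types,
            samples_per_group >= 1L,
            density > 0, density <= 1,
            effect_size >= 1,
            sigma >= 0, dropout >= 0, dropout <= 1, base_sdlog >= 0)
  structure(list(n_cell_types = as.integer(n_cell_types),
                 n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 density = density, effect_size = effect_size,
                 sigma = sigma, dropout = dropout,
                 base_sdlog = base_sdlog, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known group labels
#'
#' Draws the shared edge set, baseline edge means, group effects and
#' per-sample noise described by [cohort_spec()].  With `sigma = 0`,
#' `dropout = 0` and `effect_size = 1` all samples are identical; the same
#' seed always reproduces the same cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (a [ccc_cohort()] whose `labels` field carries
#'   the group) and `true_labels` (named character vector).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cells <- sprintf("CT%02d", seq_len(spec$n_cell_types))
  grid <- expand.grid(source = cells, target = cells,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$source, grid$target, method = "radix"), ]
  keep <- runif(nrow(grid)) < spec$density
  edges <- grid[keep, , drop = FALSE]
  if (!nrow(edges)) stop("no edges drawn; increase 'density'")
  E <- nrow(edges)
  base_mean <- rlnorm(E, meanlog = 0, sdlog = spec$base_sdlog)

  hubs <- cells[seq_len(spec$n_groups)]
  touches <- function(h) edges$source == h | edges$target == h
  hub_any <- Reduce(`|`, lapply(hubs, touches))
  affected <- lapply(seq_len(spec$n_groups), function(g) {
    mine <- touches(hubs[g])
    others <- hub_any & !mine
    which(mine & !others)
  })
  if (any(!lengths(affected)))
    stop("a group has no affected edges at this density; increase 'density'")

  n <- spec$n_groups * spec$samples_per_group
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(seq_len(spec$n_groups), each = spec$samples_per_group)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- base_mean
    mu[affected[[group[i]]]] <- mu[affected[[group[i]]]] * spec$effect_size
    w <- mu * rlnorm(E, meanlog = 0, sdlog = spec$sigma)
    present <- if (spec$dropout > 0) runif(E) >= spec$dropout
               else rep(TRUE, E)
    if (!any(present)) present[which.max(w)] <- TRUE
    samples[[i]] <- ccc_graph(ids[i],
                              data.frame(source = edges$source[present],
                                         target = edges$target[present],
                                         weight = w[present],
                                         stringsAsFactors = FALSE),
                              nodes = cells)
  }
  labels <- stats::setNames(paste0("g", group), ids)
  list(cohort = ccc_cohort(samples, labels = labels), true_labels = labels)
}

#' Binomial thinning of cohort edge weights
#'
#' Emulates sequencing fewer cells per sample: each edge weight `w` is
#' treated as a count at resolution `scale` and replaced by
#' `rbinom(1, round(w * scale), keep_fraction) / scale`, so the expected
#' weight shrinks to `keep_fraction * w` and the relative noise grows as the
#' retained signal shrinks.  Edges thinned to zero are removed from the
#' sample; the node set is preserved.
#'
#' @param cohort A [ccc_cohort()].
#' @param keep_fraction Fraction of signal kept, in `(0, 1]`.
#' @param seed RNG seed; the same seed reproduces the same thinned cohort.
#' @param scale Count resolution per unit weight.
#' @return A new [ccc_cohort()] with the same samples and labels.
#' @export
downsample_signal <- function(cohort, keep_fraction, seed = 1L,
                              scale = 100) {
  stopifnot(inherits(cohort, "ccc_cohort"))
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must lie in (0, 1]")
  set.seed(as.integer(seed))
  thinned <- lapply(cohort$samples, function(g) {
    counts <- round(g$edges$weight * scale)
    w <- rbinom(length(counts), counts, keep_fraction) / scale
    keep <- w > 0
    if (!any(keep)) {                 # keep a minimal signal in the sample
      top <- which.max(g$edges$weight)
      w[top] <- 1 / scale
      keep[top] <- TRUE
    }
    ccc_graph(g$sample_id,
              data.frame(source = g$edges$source[keep],
                         target = g$edges$target[keep],
                         weight = w[keep], stringsAsFactors = FALSE),
              nodes = g$nodes)
  })
  ccc_cohort(unname(thinned), labels = cohort$labels)
}
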