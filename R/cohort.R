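#' Construct a single-sample cell-cell communication graph
#'
#' A CCC graph holds one sample's directed, weighted cell-type interaction
#' network: nodes are cell types and a directed edge `source -> target`
#' carries the summed ligand-receptor interaction score between that ordered
#' pair of cell types.  Self-loops (a cell type signalling to itself) are
#' allowed.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param edges Data frame with character columns `source`, `target` and a
#'   numeric column `weight` (finite, non-negative).  One row per directed
#'   cell-type pair; duplicates are an error (sum ligand-receptor level rows
#'   with [aggregate_lr_scores()] first).
#' @param nodes Optional character vector of cell types; must contain every
#'   edge endpoint.  Defaults to the endpoints themselves.
#'
#' @return An object of class `ccc_graph`: a list with elements `sample_id`,
#'   `nodes` (sorted) and `edges` (data frame sorted by source then target).
#' @examples
#' g <- ccc_graph("s1", data.frame(source = "A", target = "B", weight = 2))
#' @export
ccc_graph <- function(sample_id, edges, nodes = NULL) {
  stopifnot(is.character(sample_id) || is.factor(sample_id),
            length(sample_id) == 1L)
  sample_id <- as.character(sample_id)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "weight")
  miss <- setdiff(req, names(edges))
  if (length(miss))
    stop("edges is missing required column(s): ", paste(miss, collapse = ", "))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!is.numeric(edges$weight) || anyNA(edges$weight) ||
      any(!is.finite(edges$weight)))
    stop("edge weights must be finite numerics")
  if (any(edges$weight < 0))
    stop("edge weights must be non-negative")
  lab <- .edge_label(edges$source, edges$target)
  if (anyDuplicated(lab))
    stop("duplicate directed edge(s) in sample '", sample_id, "': ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  endpoints <- unique(c(edges$source, edges$target))
  if (any(grepl(.EDGE_SEP, endpoints, fixed = TRUE)))
    stop("cell-type labels must not contain '", .EDGE_SEP, "'")
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- as.character(nodes)
    if (!all(endpoints %in% nodes))
      stop("edges reference cell types absent from 'nodes'")
  }
  ord <- order(edges$source, edges$target, method = "radix")
  edges <- edges[ord, req, drop = FALSE]
  rownames(edges) <- NULL
  structure(list(sample_id = sample_id,
                 nodes = sort(unique(nodes), method = "radix"),
                 edges = edges),
            class = "ccc_graph")
}

#' @export
print.ccc_graph <- function(x, ...) {
  cat("<ccc_graph> sample", x$sample_id, "-", length(x$nodes), "cell types,",
      nrow(x$edges), "directed edges, total weight",
      format(sum(x$edges$weight)), "\n")
  invisible(x)
}

#' Assemble a cohort of CCC graphs
#'
#' @param samples List of [ccc_graph()] objects with unique sample ids.
#' @param labels Optional class labels: a vector named by sample id, or
#'   unnamed in sample order.
#' @return Object of class `ccc_cohort` with elements `samples` (ordered by
#'   sample id), `node_universe` (sorted union of cell types) and `labels`.
#' @export
ccc_cohort <- function(samples, labels = NULL) {
  if (!length(samples) || !all(vapply(samples, inherits, TRUE, "ccc_graph")))
    stop("'samples' must be a non-empty list of ccc_graph objects")
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids, method = "radix")
  samples <- samples[ord]
  ids <- ids[ord]
  names(samples) <- ids
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!all(ids %in% names(labels)))
        stop("labels are missing for sample(s): ",
             paste(setdiff(ids, names(labels)), collapse = ", "))
      labels <- labels[ids]
    } else {
      if (length(labels) != length(ids))
        stop("unnamed labels must have one entry per sample")
      labels <- stats::setNames(labels[ord], ids)
    }
  }
  universe <- sort(unique(unlist(lapply(samples, `[[`, "nodes"),
                                 use.names = FALSE)), method = "radix")
  structure(list(samples = samples, node_universe = universe,
                 labels = labels),
            class = "ccc_cohort")
}

#' @export
print.ccc_cohort <- function(x, ...) {
  ne <- length(.cohort_edge_union(x))
  cat("<ccc_cohort>", length(x$samples), "samples,",
      length(x$node_universe), "cell types,", ne, "distinct directed edges\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# sorted union of directed-edge labels across the cohort
.cohort_edge_union <- function(cohort) {
  labs <- unlist(lapply(cohort$samples, function(g)
    .edge_label(g$edges$source, g$edges$target)), use.names = FALSE)
  sort(unique(labs), method = "radix")
}

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))) >=
      lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))) "\t" else ","
}

.read_delim_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .sniff_delim(path)
  read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.check_columns <- function(tab, required, what) {
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
}

.parse_weights <- function(x, col) {
  w <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(w) | !is.finite(w))
  if (length(bad))
    stop("non-numeric or missing ", col, " at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  neg <- which(w < 0)
  if (length(neg))
    stop("negative ", col, " at row(s): ",
         paste(utils::head(neg, 5L), collapse = ", "))
  w
}

.warn_rare_nodes <- function(cohort) {
  p <- length(cohort$samples)
  counts <- table(unlist(lapply(cohort$samples, `[[`, "nodes"),
                         use.names = FALSE))
  rare <- names(counts)[counts < p / 2]
  if (length(rare))
    warning("cell type(s) present in fewer than half of the samples ",
            "(check label harmonization): ", paste(rare, collapse = ", "),
            call. = FALSE)
  cohort
}

# shared tail of the two readers: per-sample graphs from a validated table
.cohort_from_long_table <- function(tab, labels = NULL) {
  keep <- tab$weight > 0          # a 0-weight edge is an absent edge
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab))
    stop("no edges with positive weight in the input")
  graphs <- lapply(split(tab, tab$sample), function(d)
    ccc_graph(as.character(d$sample[1L]),
              d[, c("source", "target", "weight")]))
  .warn_rare_nodes(ccc_cohort(unname(graphs), labels = labels))
}

#' Read a cohort from a delimited edge table
#'
#' Accepts either one "long" CSV/TSV with columns `sample`, `source`,
#' `target`, `weight`, or a directory containing one file per sample (columns
#' `source`, `target`, `weight`; the file name without extension becomes the
#' sample id).  The delimiter is auto-detected between comma and tab unless
#' given.  Cell-type labels are opaque, case-sensitive strings; rows with
#' weight 0 are dropped; duplicate `(sample, source, target)` rows are an
#' error (ligand-receptor level tables belong in [aggregate_lr_scores()]).
#'
#' @param path Path to a delimited file or a directory of per-sample files,
#'   or a data frame already in the long layout.
#' @param delim Field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @param labels Optional sample class labels (named by sample id).
#' @return A [ccc_cohort()] with samples and nodes in lexicographic order,
#'   so that downstream matrices are reproducible run to run.
#' @export
read_edge_table <- function(path, delim = NULL, labels = NULL) {
  if (is.data.frame(path)) {
    tab <- path
  } else if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE), method = "radix")
    if (!length(files)) stop("directory contains no files: ", path)
    parts <- lapply(files, function(f) {
      d <- .read_delim_table(f, delim)
      .check_columns(d, c("source", "target", "weight"), basename(f))
      d$sample <- sub("\\.[^.]*$", "", basename(f))
      d
    })
    tab <- do.call(rbind, parts)
  } else if (file.exists(path)) {
    tab <- .read_delim_table(path, delim)
  } else {
    stop("input not found: ", path)
  }
  .check_columns(tab, c("sample", "source", "target", "weight"), "edge table")
  tab$sample <- as.character(tab$sample)
  tab$source <- as.character(tab$source)
  tab$target <- as.character(tab$target)
  tab$weight <- .parse_weights(tab$weight, "weight")
  key <- paste(tab$sample, .edge_label(tab$source, tab$target), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, source, target) row(s), e.g. at row ",
         which(duplicated(key))[1L],
         "; use aggregate_lr_scores() for ligand-receptor level input")
  .cohort_from_long_table(tab, labels = labels)
}

#' Aggregate a ligand-receptor score table into a cohort
#'
#' Edge weights of the per-sample CCC graph are the sum of all
#' ligand-receptor interaction scores (LRScore) observed for a directed
#' cell-type pair, so a table with one row per
#' `(sample, source, target, ligand, receptor)` collapses to one weight per
#' `(sample, source, target)`.
#'
#' @param lr_table Data frame or file path with columns `sample`, `source`,
#'   `target`, `ligand`, `receptor`, `score` (scores non-negative).
#' @param delim Field delimiter for file input; `NULL` auto-detects.
#' @param labels Optional sample class labels.
#' @return A [ccc_cohort()].
#' @export
aggregate_lr_scores <- function(lr_table, delim = NULL, labels = NULL) {
  tab <- if (is.data.frame(lr_table)) lr_table
         else .read_delim_table(lr_table, delim)
  .check_columns(tab,
                 c("sample", "source", "target", "ligand", "receptor", "score"),
                 "LR table")
  tab$score <- .parse_weights(tab$score, "score")
  agg <- aggregate(score ~ sample + source + target, data = tab, FUN = sum)
  names(agg)[names(agg) == "score"] <- "weight"
  .cohort_from_long_table(agg, labels = labels)
}

#' Build the samples-by-edges signal matrix
#'
#' Rows are samples, columns the union of directed edges across the cohort
#' (labelled `"source->target"`, lexicographic order); entries are edge
#' weights, zero where a sample lacks an edge.  Each row is one sample's
#' communication signal over the shared edge set and is what optimal
#' transport compares after per-sample normalization.
#'
#' @param cohort A [ccc_cohort()].
#' @return Numeric matrix with sample ids as row names and edge labels as
#'   column names.
#' @export
build_edge_signal_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "ccc_cohort"))
  edges <- .cohort_edge_union(cohort)
  if (!length(edges)) stop("cohort has no edges")
  M <- matrix(0, nrow = length(cohort$samples), ncol = length(edges),
              dimnames = list(names(cohort$samples), edges))
  for (g in cohort$samples)
    M[g$sample_id, .edge_label(g$edges$source, g$edges$target)] <-
      g$edges$weight
  M
}

#' Write a cohort back to the long edge-table dialect
#'
#' @param cohort A [ccc_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ccc_cohort"))
  rows <- lapply(cohort$samples, function(g)
    data.frame(sample = g$sample_id, g$edges, stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Writers for derived artifacts
#'
#' `write_distance_matrix()` writes a square CSV with sample ids as header
#' and first column; `write_labels()` a two-column `(sample_id, cluster)`
#' CSV; `write_signal_edges()` a distribution over STG nodes (a barycenter
#' or a sample signal) as an edge list `(source, target, mass)`;
#' `write_transport_plan()` a transport map as long-format
#' `(source_edge, target_edge, mass)` keeping strictly positive entries.
#'
#' @param D Square numeric matrix with matching dimnames.
#' @param labels Vector named by sample id (or with `sample_ids` given).
#' @param mu Numeric vector named by `"source->target"` edge labels.
#' @param plan Matrix with edge labels as dimnames (e.g. from
#'   [wasserstein()]).
#' @param path Output CSV path.
#' @param sample_ids Optional ids when `labels` is unnamed.
#' @return `path`, invisibly.
#' @name cohort-writers
NULL

#' @rdname cohort-writers
#' @export
write_distance_matrix <- function(D, path) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  write.csv(as.data.frame(D), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-writers
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids))
    stop("labels must be named by sample id (or pass sample_ids)")
  write.csv(data.frame(sample_id = sample_ids, cluster = unname(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-writers
#' @export
write_signal_edges <- function(mu, path) {
  if (is.null(names(mu))) stop("'mu' must be named by edge labels")
  ends <- .split_edge_labels(names(mu))
  write.csv(data.frame(source = ends$source, target = ends$target,
                       mass = unname(mu)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-writers
#' @export
write_transport_plan <- function(plan, path) {
  stopifnot(is.matrix(plan))
  if (is.null(rownames(plan)) || is.null(colnames(plan)))
    stop("'plan' must carry edge labels as dimnames")
  idx <- which(plan > 0, arr.ind = TRUE)
  out <- data.frame(source_edge = rownames(plan)[idx[, 1L]],
                    target_edge = colnames(plan)[idx[, 2L]],
                    mass = plan[idx])
  out <- out[order(-out$mass), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
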