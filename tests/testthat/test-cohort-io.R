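test_that("edge tables parse into canonically ordered cohorts", {
  tab <- edge_table_df()
  co <- read_edge_table(tab)
  expect_s3_class(co, "ccc_cohort")
  expect_length(co$samples, 2L)
  expect_identical(names(co$samples), c("s1", "s2"))
  expect_identical(co$node_universe, c("A", "B"))
  expect_equal(co$samples$s1$edges$weight, c(1, 2))

  # ordering is canonicalized: shuffled rows give the identical cohort
  shuffled <- tab[c(3, 1, 2), ]
  expect_identical(read_edge_table(shuffled), co)
})

test_that("parser rejects malformed input with informative errors", {
  tab <- edge_table_df()
  expect_error(read_edge_table(tab[, -4]), "weight")
  bad <- tab; bad$weight[2] <- -1
  expect_error(read_edge_table(bad), "negative weight.*2")
  nonnum <- tab; nonnum$weight <- as.character(nonnum$weight)
  nonnum$weight[3] <- "abc"
  expect_error(read_edge_table(nonnum), "row.*3")
  dup <- rbind(tab, tab[1, ])
  expect_error(read_edge_table(dup), "aggregate_lr_scores")
  expect_error(read_edge_table("/nonexistent/file.csv"), "not found")
})

test_that("zero-weight rows are dropped and rare nodes trigger a warning", {
  tab <- rbind(edge_table_df(),
               data.frame(sample = "s1", source = "A", target = "C",
                          weight = 0))
  co <- suppressWarnings(read_edge_table(tab))
  expect_false("C" %in% co$node_universe)

  rare <- rbind(edge_table_df(),
                data.frame(sample = c("s2", "s3"), source = c("Z", "A"),
                           target = c("A", "B"), weight = 1))
  expect_warning(read_edge_table(rare), "Z")
})

test_that("file and directory dialects round-trip through write_cohort", {
  sim <- small_cohort(seed = 3L)
  f <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, f)
  back <- read_edge_table(f)
  expect_equal(back$samples, sim$cohort$samples)
  expect_identical(back$node_universe, sim$cohort$node_universe)

  # one-file-per-sample directory dialect
  dir <- tempfile(); dir.create(dir)
  for (g in sim$cohort$samples)
    write.csv(g$edges, file.path(dir, paste0(g$sample_id, ".csv")),
              row.names = FALSE, quote = FALSE)
  back2 <- read_edge_table(dir)
  expect_equal(back2$samples, sim$cohort$samples)
})

test_that("LR scores aggregate to per-edge sums", {
  lr <- data.frame(sample = "s1", source = "A", target = "B",
                   ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                   score = c(0.2, 0.3))
  co <- aggregate_lr_scores(lr)
  expect_equal(co$samples$s1$edges$weight, 0.5)

  single <- aggregate_lr_scores(lr[1, ])
  expect_equal(single$samples$s1$edges$weight, 0.2)

  # 100 random rows vs an independent group-and-sum oracle
  set.seed(11)
  big <- data.frame(sample = sample(c("s1", "s2"), 100, TRUE),
                    source = sample(LETTERS[1:4], 100, TRUE),
                    target = sample(LETTERS[1:4], 100, TRUE),
                    ligand = sample(paste0("L", 1:6), 100, TRUE),
                    receptor = sample(paste0("R", 1:6), 100, TRUE),
                    score = runif(100))
  co <- aggregate_lr_scores(big)
  expected <- tapply(big$score,
                     paste(big$sample, big$source, big$target), sum)
  for (g in co$samples) {
    key <- paste(g$sample_id, g$edges$source, g$edges$target)
    expect_equal(g$edges$weight, as.vector(expected[key]))
  }
})

test_that("signal matrix is zero-padded, ordered, and mass-preserving", {
  g1 <- ccc_graph("s1", data.frame(source = c("A", "B"),
                                   target = c("B", "C"),
                                   weight = c(1, 2)))
  g2 <- ccc_graph("s2", data.frame(source = "A", target = "B", weight = 5))
  M <- build_edge_signal_matrix(ccc_cohort(list(g1, g2)))
  expect_identical(dim(M), c(2L, 2L))
  expect_identical(colnames(M), c("A->B", "B->C"))
  expect_equal(M["s2", "B->C"], 0)
  expect_equal(M["s1", ], c(`A->B` = 1, `B->C` = 2))

  # one sample: the matrix is that sample's weight vector
  M1 <- build_edge_signal_matrix(ccc_cohort(list(g1)))
  expect_equal(as.vector(M1), g1$edges$weight)

  # direction matters: A->B and B->A are distinct columns
  gd <- ccc_graph("s3", data.frame(source = c("A", "B"),
                                   target = c("B", "A"), weight = c(1, 9)))
  Md <- build_edge_signal_matrix(ccc_cohort(list(gd)))
  expect_identical(colnames(Md), c("A->B", "B->A"))

  # row sums equal per-sample total edge weight; invariant to row order
  sim <- small_cohort(seed = 5L)
  Ms <- build_edge_signal_matrix(sim$cohort)
  totals <- vapply(sim$cohort$samples, function(g) sum(g$edges$weight), 0)
  expect_equal(rowSums(Ms), totals)
  expect_true(all(colSums(Ms > 0) >= 1))
})

test_that("graph and cohort constructors enforce their invariants", {
  expect_error(ccc_graph("s", data.frame(source = "A", target = "B",
                                         weight = Inf)), "finite")
  expect_error(ccc_graph("s", data.frame(source = c("A", "A"),
                                         target = c("B", "B"),
                                         weight = c(1, 2))), "duplicate")
  expect_error(ccc_graph("s", data.frame(source = "A", target = "B",
                                         weight = 1), nodes = "A"),
               "absent")
  g <- ccc_graph("s", data.frame(source = "A", target = "B", weight = 1))
  expect_error(ccc_cohort(list(g, g)), "duplicate sample ids")
  expect_error(ccc_cohort(list()), "non-empty")
})
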