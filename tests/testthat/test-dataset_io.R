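test_that("expression_matrix validates identifiers and values", {
  m <- matrix(1:4, 2, 2)
  expect_error(expression_matrix(m, c("g1", "g1"), c("s1", "s2")), "unique")
  expect_error(expression_matrix(matrix(c(1, NA, 3, 4), 2),
                                 c("g1", "g2"), c("s1", "s2")), "missing")
  em <- expression_matrix(m, c("g1", "g2"), c("s1", "s2"))
  expect_identical(colnames(em), c("g1", "g2"))
  expect_identical(dim(em), c(2L, 2L))
})

test_that("gene filtering drops genes that are lowly expressed AND flat", {
  em <- expression_matrix(
    cbind(low_flat = c(0.5, 0.5, 0.5),   # max 0.5 < 1, var 0 < 0.8
          expressed = c(0, 0, 2),        # passes the expression rule
          variable = c(0, 0.1, 2.6)),    # max 2.6 also variable
    sample_ids = c("s1", "s2", "s3"))
  kept <- filter_genes(em, min_expr = 1, min_var = 0.8)
  expect_identical(colnames(kept), c("expressed", "variable"))

  # exhaustive per-gene oracle on a random matrix
  withr::with_seed(99, {
    m <- matrix(runif(20 * 10, 0, 2), 20, 10)
    em2 <- expression_matrix(m, sprintf("g%d", 1:10), sprintf("s%d", 1:20))
  })
  kept2 <- filter_genes(em2, min_expr = 1.8, min_var = 0.3)
  oracle <- vapply(seq_len(10), function(j) {
    !(max(m[, j]) < 1.8 && var(m[, j]) < 0.3)
  }, logical(1))
  expect_identical(colnames(kept2), sprintf("g%d", which(oracle)))

  expect_error(filter_genes(em2, min_expr = 100, min_var = 1e6), "all genes")
})

test_that("select_hvg keeps the top-variance genes, ties by input order", {
  em <- toy_expr(n = 12L, p = 10L)
  expect_identical(select_hvg(em, 10L), em)
  top3 <- select_hvg(em, 3L)
  vars <- apply(unclass(em), 2, var)
  expect_setequal(colnames(top3),
                  colnames(em)[order(-vars)][1:3])
  # equal variance at the cutoff: earlier gene wins
  tied <- expression_matrix(cbind(a = c(0, 1), b = c(5, 6), c = c(2, 3)),
                            sample_ids = c("s1", "s2"))
  expect_identical(colnames(select_hvg(tied, 2L)), c("a", "b"))
  expect_error(select_hvg(em, 0), "positive")
  expect_error(select_hvg(em, 99), "exceeds")
})

test_that("filtering then HVG selection equals the one-pass combined rule", {
  for (s in 1:5) {
    em <- toy_expr(n = 15L, p = 12L, seed = s)
    res <- select_hvg(filter_genes(em, 1.5, 0.5), 4L)
    m <- unclass(em)
    keep <- which(!(apply(m, 2, max) < 1.5 & apply(m, 2, var) < 0.5))
    vars <- apply(m[, keep, drop = FALSE], 2, var)
    oracle <- keep[sort(order(-vars, seq_along(vars))[1:4])]
    expect_identical(colnames(res), colnames(em)[oracle])
  }
})

test_that("control pairing strategies are reproducible and correct", {
  ctrl <- toy_expr(n = 3L, p = 4L)
  pert <- toy_expr(n = 6L, p = 4L, seed = 1L)
  p1 <- pair_controls(pert, ctrl, "random_control", seed = 5L)
  p2 <- pair_controls(pert, ctrl, "random_control", seed = 5L)
  expect_identical(p1$pairing, p2$pairing)
  expect_true(all(p1$pairing %in% 1:3))

  one <- em_subset(ctrl, i = 1L)
  expect_true(all(pair_controls(pert, one)$pairing == 1L))

  two <- em_subset(ctrl, i = 1:2)
  pm <- pair_controls(pert, two, "mean_control")
  expect_equal(unclass(pm$controls)[pm$pairing[1], ],
               colMeans(unclass(two)))
  none <- expression_matrix(matrix(numeric(0), 0, 4),
                            gene_ids = colnames(ctrl),
                            sample_ids = character(0))
  expect_error(pair_controls(pert, none), "empty")
})

test_that("screens round-trip through csv and mtx identically", {
  sim <- simulate_screen(synth_config(n_genes = 12L, n_perturbations = 3L,
                                      n_cells_per_condition = 4L,
                                      n_controls = 5L, seed = 21L))
  screen <- sim$screen
  dir_csv <- withr::local_tempdir()
  dir_mtx <- withr::local_tempdir()
  paths_csv <- write_screen(screen, dir_csv, "csv")
  paths_mtx <- write_screen(screen, dir_mtx, "mtx")

  back_csv <- load_screen(paths_csv$expr, paths_csv$design, paths_csv$outcome,
                          "csv")
  back_mtx <- load_screen(paths_mtx$expr, paths_mtx$design, paths_mtx$outcome,
                          "mtx")
  expect_equal(unclass(back_csv$controls), unclass(screen$controls),
               ignore_attr = FALSE)
  expect_equal(unclass(back_csv$outcomes), unclass(screen$outcomes))
  expect_identical(back_csv$design$matrix, screen$design$matrix)
  expect_identical(back_csv$pairing, screen$pairing)
  # cross-format equality
  expect_equal(unclass(back_mtx$controls), unclass(back_csv$controls))
  expect_equal(unclass(back_mtx$outcomes), unclass(back_csv$outcomes))
  expect_identical(back_mtx$pairing, back_csv$pairing)
})

test_that("loading fails loudly on unresolvable identifiers", {
  screen <- toy_screen()
  dir <- withr::local_tempdir()
  paths <- write_screen(screen, dir, "csv")
  # corrupt the design: reference a control absent from the expression data
  d <- read.csv(paths$design, check.names = FALSE)
  d$control_id[2] <- "ghost"
  write.csv(d, paths$design, row.names = FALSE, quote = FALSE)
  expect_error(load_screen(paths$expr, paths$design, paths$outcome, "csv"),
               "ghost")
})

test_that("scalar-outcome screens survive a round trip", {
  sim <- simulate_synergy_screen(synth_config(n_genes = 10L,
                                              n_perturbations = 4L,
                                              n_cell_lines = 6L, seed = 3L))
  dir <- withr::local_tempdir()
  paths <- write_screen(sim$screen, dir, "csv")
  back <- load_screen(paths$expr, paths$design, paths$outcome, "csv")
  expect_identical(back$outcome_kind, "scalar")
  expect_equal(back$outcomes, sim$screen$outcomes)
  expect_identical(back$design$matrix, sim$screen$design$matrix)
})
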