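test_that("encoding is deterministic, batch-consistent and shaped", {
  m <- small_model()
  x <- withr::with_seed(1, matrix(rnorm(12), 2, 6))
  expect_identical(encode(m, x[1, ]), encode(m, x[1, ]))
  batch <- encode(m, x)
  expect_equal(batch[1, , drop = FALSE], encode(m, x[1, ]))
  expect_equal(batch[2, , drop = FALSE], encode(m, x[2, ]))
  for (d in c(2L, 5L)) {
    ms <- small_model(latent = d)
    expect_identical(ncol(encode(ms, x[1, ])), d)
  }
  expect_error(encode(m, rnorm(4)), "does not match")
})

test_that("identical config and seed give identical parameters and predictions", {
  m1 <- small_model(seed = 123L)
  m2 <- small_model(seed = 123L)
  expect_identical(codex_flatten(m1), codex_flatten(m2))
  x <- withr::with_seed(2, rnorm(6))
  p1 <- codex_forward(m1, x, c(1, 1, 0))
  p2 <- codex_forward(m2, x, c(1, 1, 0))
  expect_identical(p1, p2)
})

test_that("branch maps respect dose conventions and shapes", {
  md <- small_model(dose_transform = "log10_minmax",
                    dose_levels = c(0.1, 1, 10))
  h <- withr::with_seed(3, rnorm(4))
  # sentinel (no dose) and the lowest training dose encode identically
  expect_identical(branch_apply(md, h, 1L, dose = 0.1),
                   branch_apply(md, h, 1L))
  # distinct doses give distinct branch inputs
  expect_false(isTRUE(all.equal(branch_apply(md, h, 1L, dose = 10),
                                branch_apply(md, h, 1L, dose = 0.1))))
  expect_identical(ncol(branch_apply(md, h, 2L, dose = 1)), 4L)
  m <- small_model()
  expect_error(branch_apply(m, h, 1L, dose = 5), "undosed")
  expect_error(branch_apply(m, h, 9L), "invalid")
})

test_that("aggregation is a weighted sum, permutation-invariant, empty-sum zero", {
  m <- small_model()
  h <- encode(m, withr::with_seed(4, rnorm(6)))
  b1 <- branch_apply(m, h, 1L)
  b2 <- branch_apply(m, h, 2L)
  outs <- list(P1 = b1, P2 = b2)
  w <- c(P1 = 1, P2 = 1, P3 = 0)
  z12 <- aggregate_branches(outs, w)
  z21 <- aggregate_branches(outs[c("P2", "P1")], w)
  expect_equal(z12, b1 + b2)
  expect_equal(z12, z21)
  expect_equal(aggregate_branches(list(P1 = b1), c(P1 = 1, P2 = 0, P3 = 0)),
               b1)
  expect_equal(aggregate_branches(list(), c(0, 0, 0), latent_dim = 4L),
               matrix(0, 1, 4))
})

test_that("skipping zero-weight branches matches all-branch evaluation", {
  withr::with_seed(17, {
    # single instances: the skipped and the all-branch path execute the
    # same floating-point sequence, so results are bitwise equal
    for (i in 1:8) {
      head <- if (i %% 2 == 0) "scalar" else "gaussian"
      m <- small_model(head = head, K = 4L, seed = i)
      x <- rnorm(6, 2)
      t <- rbinom(4, 1, 0.5)
      expect_identical(codex_forward(m, x, t), naive_forward(m, x, t))
    }
    # batches: row-subset evaluation may reorder BLAS arithmetic, so the
    # equivalence is checked numerically
    m <- small_model(head = "gaussian", K = 4L, seed = 99L)
    x <- matrix(rnorm(18, 2), 3, 6)
    t <- matrix(rbinom(12, 1, 0.5), 3, 4)
    expect_equal(codex_forward(m, x, t), naive_forward(m, x, t))
  })
})

test_that("one-hot forward equals decoding a single branch", {
  m <- small_model(head = "gaussian")
  x <- withr::with_seed(5, rnorm(6, 2))
  via_forward <- codex_forward(m, x, c(0, 1, 0))
  manual <- decode_gaussian(m, branch_apply(m, encode(m, x), 2L))
  expect_identical(via_forward, manual)
})

test_that("fractional proxy rows decode the weighted branch mixture", {
  m <- small_model(head = "gaussian", K = 5L)
  x <- withr::with_seed(6, rnorm(6, 2))
  w <- c(0, 0.4, 0.35, 0.25, 0)
  h <- encode(m, x)
  z <- 0.4 * branch_apply(m, h, 2L) + 0.35 * branch_apply(m, h, 3L) +
    0.25 * branch_apply(m, h, 4L)
  expect_equal(codex_forward(m, x, w), decode_gaussian(m, z))
})

test_that("aggregation is linear in the weight vector at the latent level", {
  m <- small_model(head = "gaussian")
  x <- withr::with_seed(7, rnorm(6, 2))
  h <- encode(m, x)
  outs <- list(P1 = branch_apply(m, h, 1L), P2 = branch_apply(m, h, 2L),
               P3 = branch_apply(m, h, 3L))
  t1 <- c(P1 = 1, P2 = 0, P3 = 0)
  t2 <- c(P1 = 0, P2 = 1, P3 = 1)
  a <- 0.3; b <- 1.7
  z_comb <- aggregate_branches(outs, a * t1 + b * t2)
  z_sep <- a * aggregate_branches(outs, t1) + b * aggregate_branches(outs, t2)
  expect_equal(z_comb, z_sep)
  expect_equal(decode_gaussian(m, z_comb), codex_forward(m, x, a * t1 + b * t2))
})

test_that("decoded variances are floored at the configured epsilon", {
  m <- small_model(head = "gaussian")
  # force the variance half of the head to a hugely negative log-variance
  L <- length(m$decoder)
  m$decoder[[L]]$b[6 + 1:6] <- -100
  out <- decode_gaussian(m, rnorm(4))
  expect_true(all(out$sigma2 == 1e-6))
  # and across many random models/latents the floor always holds
  withr::with_seed(8, {
    for (i in 1:20) {
      mi <- small_model(head = "gaussian", seed = 1000L + i)
      oi <- decode_gaussian(mi, matrix(rnorm(40, sd = 5), 10, 4))
      expect_true(all(oi$sigma2 >= 1e-6))
    }
  })
})

test_that("head mismatches error", {
  m <- small_model(head = "gaussian")
  expect_error(decode_scalar(m, rnorm(4)), "scalar-head")
  ms <- small_model(head = "scalar")
  expect_error(decode_gaussian(ms, rnorm(4)), "gaussian-head")
})

test_that("checkpoints round-trip the model", {
  m <- small_model(head = "gaussian", dose_transform = "log10_minmax",
                   dose_levels = c(0.5, 5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_codex(m, path)
  back <- load_codex(path)
  expect_identical(codex_flatten(back), codex_flatten(m))
  expect_identical(back$perturbation_ids, m$perturbation_ids)
  expect_identical(back$dose_levels, m$dose_levels)
  x <- withr::with_seed(9, rnorm(6, 2))
  expect_identical(codex_forward(back, x, c(1, 0, 0), c(5, 0, 0)),
                   codex_forward(m, x, c(1, 0, 0), c(5, 0, 0)))
})
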