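test_that("linear baseline averages the single-perturbation mean profiles", {
  screen <- toy_screen()
  y <- unclass(screen$outcomes)
  expect_equal(linear_baseline(screen, "A"), y[1, ])
  expect_equal(linear_baseline(screen, c("A", "B")), (y[1, ] + y[2, ]) / 2)
  expect_equal(linear_baseline(screen, c("A", "B", "C")),
               (y[1, ] + y[2, ] + y[4, ]) / 3)
  expect_error(linear_baseline(screen, "Z"), "no single-perturbation")
})

test_that("lin-CODEX averages one-hot forward passes", {
  m <- small_model(head = "gaussian")
  x <- withr::with_seed(51, rnorm(6, 2))
  single <- lincodex_predict(m, x, "P2")
  expect_equal(drop(single), drop(codex_forward(m, x, c(0, 1, 0))$mu))
  pair <- lincodex_predict(m, x, c("P1", "P3"))
  oracle <- (codex_forward(m, x, c(1, 0, 0))$mu +
             codex_forward(m, x, c(0, 0, 1))$mu) / 2
  expect_equal(pair, oracle)
  expect_error(lincodex_predict(m, x, character(0)), "empty")
  expect_error(lincodex_predict(m, x, "Q9"), "unknown")
})

test_that("lin-CODEX differs from the full forward under a nonlinear decoder", {
  sim <- simulate_screen(synth_config(
    n_genes = 40L, n_perturbations = 3L, n_cells_per_condition = 60L,
    interaction_pairs = data.frame(k = 1, l = 2, gamma = 2),
    seed = 15L))
  cfg <- codex_config(latent_dim = 8L, encoder_widths = 16L,
                      decoder_widths = 16L, head = "gaussian", seed = 2L)
  model <- codex_model(cfg, 40L, sim$screen$design$perturbation_ids, 40L)
  fit <- train_codex(model, sim$screen,
                     cfg = train_config(epochs = 60L, seed = 3L))
  x <- colMeans(unclass(sim$screen$controls))
  full <- codex_forward(fit$model, x, c(1, 1, 0))$mu
  avg <- lincodex_predict(fit$model, x, c("P1", "P2"))
  expect_gt(max(abs(full - avg)), 1e-3)
})

test_that("effect-sum ablation equals the full forward for an affine decoder", {
  cfg <- codex_config(latent_dim = 4L, encoder_widths = 5L,
                      branch_widths = integer(0),
                      decoder_widths = integer(0),   # single affine layer
                      head = "gaussian", seed = 21L)
  m <- codex_model(cfg, 6L, c("P1", "P2", "P3"), 6L)
  x <- withr::with_seed(52, matrix(rnorm(12, 2), 2, 6))
  full <- codex_forward(m, x, c(1, 1, 0))$mu
  abl <- lincodex_predict(m, x, c("P1", "P2"), mode = "effect_sum")
  expect_equal(abl, full)
  # three-way combination, same identity
  full3 <- codex_forward(m, x, c(1, 1, 1))$mu
  abl3 <- lincodex_predict(m, x, c("P1", "P2", "P3"), mode = "effect_sum")
  expect_equal(abl3, full3)
  # with a nonlinear decoder the two generally differ
  mn <- small_model(head = "gaussian")
  xf <- withr::with_seed(53, rnorm(6, 2))
  expect_false(isTRUE(all.equal(
    lincodex_predict(mn, xf, c("P1", "P2"), mode = "effect_sum"),
    codex_forward(mn, xf, c(1, 1, 0))$mu)))
})

test_that("random baseline returns the centroid or a reproducible draw", {
  screen <- toy_screen()
  expect_equal(random_baseline(screen),
               colMeans(unclass(screen$controls)))
  s1 <- random_baseline(screen, seed = 4L, strategy = "sampled")
  s2 <- random_baseline(screen, seed = 4L, strategy = "sampled")
  expect_identical(s1, s2)
  one <- perturb_screen(
    expression_matrix(matrix(1:6, 1, 6,
                             dimnames = list("c1", sprintf("g%d", 1:6)))),
    screen$design, screen$outcomes, rep(1L, 4))
  expect_equal(unname(random_baseline(one)), as.numeric(1:6))
})

test_that("top_k_degs ranks by absolute mean difference with stable ties", {
  ctrl <- rep(0, 6)
  pert <- c(0, 3, 1, -4, 2, 0)
  expect_identical(top_k_degs(pert, ctrl, 2L), c(4L, 2L))
  expect_identical(sort(top_k_degs(pert, ctrl, 6L)), 1:6)
  expect_identical(top_k_degs(ctrl, ctrl, 3L), 1:3)
  expect_error(top_k_degs(pert, ctrl, 0), "positive")
})

test_that("eval_condition matches textbook formulas on a toy case", {
  control <- c(1, 1, 1, 1, 1)
  truth <- rbind(c(2, 0, 1, 3, 1), c(2, 2, 1, 5, 1))  # mean (2,1,1,4,1)
  tm <- colMeans(truth)
  pred <- c(1.5, 1.0, 1.5, 3.0, 1.0)
  ev <- eval_condition(pred, truth, control, k = 2L)
  expect_equal(ev$r2_all, 1 - sum((pred - tm)^2) / sum((tm - mean(tm))^2))
  expect_equal(ev$pcc_all, cor(pred, tm))
  expect_equal(ev$scc_all, cor(pred, tm, method = "spearman"))
  expect_equal(ev$pcc_effect, cor(pred - control, tm - control))
  # top-2 DEGs are genes 4 (|3|) and 1 (|1|)
  degs <- c(4L, 1L)
  expect_equal(ev$nmse_topk,
               mean((pred[degs] - tm[degs])^2) /
                 mean((control[degs] - tm[degs])^2))
  expect_equal(ev$mse_all, mean((pred - tm)^2))

  perfect <- eval_condition(tm, truth, control, k = 3L)
  expect_equal(perfect$r2_all, 1)
  expect_equal(perfect$pcc_all, 1)
  expect_equal(perfect$nmse_topk, 0)

  # the baseline normalized against itself scores exactly 1
  self <- eval_condition(control, truth, control, k = 3L)
  expect_equal(self$nmse_topk, 1)
})

test_that("degenerate evaluations are reported as missing", {
  control <- rep(1, 4)
  truth <- rbind(c(2, 2, 2, 2))
  ev <- eval_condition(rep(3, 4), truth, control, k = 2L)
  expect_true(is.na(ev$pcc_all))
  expect_true(is.na(ev$r2_all))
})

test_that("normalized MSE is invariant to joint affine rescaling", {
  withr::with_seed(61, {
    control <- rnorm(20); truth <- matrix(rnorm(60), 3, 20)
    pred <- rnorm(20)
  })
  a <- 2.5; b <- -1
  ev1 <- eval_condition(pred, truth, control, k = 5L)
  ev2 <- eval_condition(a * pred + b, a * truth + b, a * control + b, k = 5L)
  expect_equal(ev1$nmse_topk, ev2$nmse_topk)
  expect_equal(ev1$pcc_all, ev2$pcc_all)
})
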