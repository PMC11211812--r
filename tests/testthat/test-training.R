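test_that("mse_loss matches hand computations and its invariances", {
  expect_identical(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mse_loss(c(0, 0), c(1, 3)), 5)
  perm <- c(2, 1, 3)
  a <- c(0.3, -1, 2); b <- c(1, 0, -0.5)
  expect_equal(mse_loss(a[perm], b[perm]), mse_loss(a, b))
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:2, 1:3), "differ")
})

test_that("gaussian_nll matches its closed forms", {
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  unit <- matrix(1, 2, 2)
  expect_equal(gaussian_nll(list(mu = y, sigma2 = unit), y), 0)
  # mu - y = r with unit variance reduces to half the summed squares
  r <- matrix(c(0.5, -1, 2, 0), 2, 2)
  expect_equal(gaussian_nll(list(mu = y + r, sigma2 = unit), y),
               sum(r^2) / 2)
  # mu = y, sigma2 = e^2: each element contributes log(e^2)/2 = 1
  expect_equal(gaussian_nll(list(mu = y, sigma2 = unit * exp(2)), y),
               length(y))
  expect_error(gaussian_nll(list(mu = y, sigma2 = unit * 0), y),
               "nonpositive")
})

test_that("gaussian_nll with unit variance and mean reduction is half the MSE", {
  withr::with_seed(31, {
    mu <- matrix(rnorm(30), 5, 6)
    y <- matrix(rnorm(30), 5, 6)
  })
  expect_equal(gaussian_nll(list(mu = mu, sigma2 = mu * 0 + 1), y, "mean"),
               mse_loss(mu, y) / 2)
})

test_that("analytic gradients match central finite differences", {
  for (head in c("gaussian", "scalar")) {
    m <- small_model(head = head, p = 5L, K = 3L, latent = 3L, seed = 5L)
    withr::with_seed(23, {
      X <- matrix(rnorm(4 * 5, 2), 4, 5)
      Tm <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 1))
      Y <- if (head == "gaussian") matrix(rnorm(4 * 5, 3), 4, 5) else
        matrix(rnorm(4), 4, 1)
    })
    lg <- codexr:::codex_loss_grad(m, X, Tm, NULL, Y)
    g_analytic <- codexr:::flatten_grads(lg$grads)
    theta <- codexr:::codex_flatten(m)
    eps <- 1e-5
    idx <- withr::with_seed(3, sample(length(theta), 60L))
    g_num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm_ <- theta; tm_[i] <- tm_[i] - eps
      lp <- codexr:::codex_loss_grad(codexr:::codex_unflatten(m, tp),
                                     X, Tm, NULL, Y, want_grad = FALSE)$loss
      lm <- codexr:::codex_loss_grad(codexr:::codex_unflatten(m, tm_),
                                     X, Tm, NULL, Y, want_grad = FALSE)$loss
      (lp - lm) / (2 * eps)
    }, numeric(1))
    denom <- pmax(abs(g_num), abs(g_analytic[idx]), 1e-8)
    expect_lt(max(abs(g_num - g_analytic[idx]) / denom), 1e-4)
  }
})

test_that("gradients flow through dosed branches too", {
  m <- small_model(head = "gaussian", p = 5L, K = 2L, latent = 3L,
                   seed = 6L, dose_transform = "log10_minmax",
                   dose_levels = c(0.1, 1, 10))
  withr::with_seed(24, {
    X <- matrix(rnorm(3 * 5, 2), 3, 5)
    Tm <- rbind(c(1, 0), c(0, 1), c(1, 1))
    D <- Tm * c(0.1, 1, 10)
    Y <- matrix(rnorm(3 * 5, 3), 3, 5)
  })
  lg <- codexr:::codex_loss_grad(m, X, Tm, D, Y)
  g_analytic <- codexr:::flatten_grads(lg$grads)
  theta <- codexr:::codex_flatten(m)
  eps <- 1e-5
  idx <- withr::with_seed(4, sample(length(theta), 40L))
  g_num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm_ <- theta; tm_[i] <- tm_[i] - eps
    lp <- codexr:::codex_loss_grad(codexr:::codex_unflatten(m, tp),
                                   X, Tm, D, Y, want_grad = FALSE)$loss
    lm <- codexr:::codex_loss_grad(codexr:::codex_unflatten(m, tm_),
                                   X, Tm, D, Y, want_grad = FALSE)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  denom <- pmax(abs(g_num), abs(g_analytic[idx]), 1e-8)
  expect_lt(max(abs(g_num - g_analytic[idx]) / denom), 1e-4)
})

test_that("training reduces the loss below the untrained model", {
  sim <- simulate_screen(synth_config(n_genes = 30L, n_perturbations = 3L,
                                      n_cells_per_condition = 40L,
                                      seed = 12L))
  screen <- sim$screen
  cfg <- codex_config(latent_dim = 8L, encoder_widths = 16L,
                      decoder_widths = 16L, head = "gaussian", seed = 1L)
  model <- codex_model(cfg, 30L, screen$design$perturbation_ids, 30L)
  tens <- codexr:::screen_tensors(screen)
  loss0 <- codexr:::codex_loss_grad(model, tens$X, tens$T, tens$D, tens$Y,
                                    want_grad = FALSE)$loss
  fit <- train_codex(model, screen,
                     cfg = train_config(epochs = 40L, seed = 2L))
  loss1 <- codexr:::codex_loss_grad(fit$model, tens$X, tens$T, tens$D,
                                    tens$Y, want_grad = FALSE)$loss
  expect_lt(loss1, loss0)
  expect_lte(fit$report$best_epoch, length(fit$report$train_loss))
})

test_that("training is bit-reproducible under a fixed seed", {
  sim <- simulate_screen(synth_config(n_genes = 20L, n_perturbations = 2L,
                                      n_cells_per_condition = 25L,
                                      seed = 13L))
  mk <- function() {
    cfg <- codex_config(latent_dim = 6L, encoder_widths = 10L,
                        decoder_widths = 10L, head = "gaussian", seed = 9L)
    codex_model(cfg, 20L, sim$screen$design$perturbation_ids, 20L)
  }
  tc <- train_config(epochs = 10L, seed = 77L)
  f1 <- train_codex(mk(), sim$screen, cfg = tc)
  f2 <- train_codex(mk(), sim$screen, cfg = tc)
  expect_identical(codexr:::codex_flatten(f1$model),
                   codexr:::codex_flatten(f2$model))
  expect_identical(f1$report$train_loss, f2$report$train_loss)
})

test_that("a scalar-head model beats the label variance on a synergy screen", {
  sim <- simulate_synergy_screen(synth_config(
    n_genes = 40L, n_perturbations = 5L, n_cell_lines = 15L,
    interaction_pairs = data.frame(k = c(1, 2, 3, 1, 2, 4),
                                   l = c(2, 3, 4, 3, 5, 5),
                                   gamma = c(4, -3, 2, 0, 5, -2)),
    synergy_noise_sd = 0.5, seed = 14L))
  screen <- sim$screen
  cfg <- codex_config(latent_dim = 8L, encoder_widths = 16L,
                      decoder_widths = 16L, head = "scalar", seed = 3L)
  model <- codex_model(cfg, 40L, screen$design$perturbation_ids)
  fit <- train_codex(model, screen,
                     cfg = train_config(epochs = 150L, seed = 4L,
                                        batch_size = 32L,
                                        early_stop_patience = 50L))
  tens <- codexr:::screen_tensors(screen)
  pred <- codex_forward(fit$model, tens$X, tens$T)
  expect_lt(mse_loss(pred, screen$outcomes), var(screen$outcomes))
})

test_that("training aborts cleanly when the screen and head disagree", {
  screen <- toy_screen()
  cfg <- codex_config(latent_dim = 4L, head = "scalar", seed = 1L)
  model <- codex_model(cfg, 6L, c("A", "B", "C"))
  expect_error(train_codex(model, screen, cfg = train_config()),
               "does not match")
})
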