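#' Mean squared error
#'
#' `(1/N) * sum((pred - target)^2)` over all elements; used as the training
#' objective of the scalar (synergy-score) head.
#'
#' @param pred,target numeric vectors or matrices of equal shape.
#' @return the mean squared error.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (length(pred) != length(target)) {
    stop("pred and target lengths differ", call. = FALSE)
  }
  mean((as.numeric(pred) - as.numeric(target))^2)
}

#' Heteroscedastic Gaussian negative log likelihood
#'
#' `sum_{i,j} 0.5 * (log(sigma2_ij) + (mu_ij - y_ij)^2 / sigma2_ij)` (the
#' constant `0.5 * log(2*pi)` term is omitted, so the loss is exactly zero
#' when `mu = y` and `sigma2 = 1`). With `reduction = "mean"` the sum is
#' divided by the number of elements, in which case freezing `sigma2 = 1`
#' reduces the loss to half the mean squared error.
#'
#' @param pred list with matrices `mu` and `sigma2` (as returned by
#'   [decode_gaussian()]).
#' @param target numeric matrix of observed profiles, same shape as `mu`.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return the loss value.
#' @export
gaussian_nll <- function(pred, target, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  mu <- as.matrix(pred$mu)
  s2 <- as.matrix(pred$sigma2)
  y <- as.matrix(target)
  if (!all(dim(mu) == dim(y)) || !all(dim(s2) == dim(y))) {
    stop("shape mismatch between prediction and target", call. = FALSE)
  }
  if (any(s2 <= 0)) stop("nonpositive variance", call. = FALSE)
  v <- 0.5 * (log(s2) + (mu - y)^2 / s2)
  if (reduction == "sum") sum(v) else mean(v)
}

#' Training configuration
#'
#' @param epochs maximum number of passes over the training triplets.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight decay.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (the best-epoch parameters are restored).
#' @param val_fraction fraction of the *training* triplets held out for
#'   early stopping (never taken from a test fold).
#' @param decoder_mlp_decay_mult multiplier on `weight_decay` for the
#'   decoder's nonlinear stack only. Values above 1 shrink the decoder's
#'   interaction correction toward the additive (residual linear path)
#'   solution unless the data support it, which protects extrapolation to
#'   unseen treatment combinations.
#' @param ema_decay exponential moving average decay for the returned
#'   parameters (0 disables). Averaging the optimizer trajectory damps
#'   minibatch noise and markedly stabilizes out-of-distribution
#'   predictions.
#' @param seed seed governing the validation split, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L,
                         learning_rate = 1e-3, weight_decay = 1e-5,
                         early_stop_patience = 25L, val_fraction = 0.1,
                         decoder_mlp_decay_mult = 1, ema_decay = 0,
                         seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            weight_decay >= 0, early_stop_patience >= 1L,
            val_fraction >= 0, val_fraction < 1,
            decoder_mlp_decay_mult >= 0,
            ema_decay >= 0, ema_decay < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 decoder_mlp_decay_mult = decoder_mlp_decay_mult,
                 ema_decay = ema_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

# assemble (X, T, D, Y) training arrays from a screen
screen_tensors <- function(screen, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_triplets(screen))
  X <- unclass(screen$controls)[screen$pairing[idx], , drop = FALSE]
  Tm <- screen$design$matrix[idx, , drop = FALSE]
  D <- if (!is.null(screen$design$dosages)) {
    screen$design$dosages[idx, , drop = FALSE]
  }
  Y <- if (screen$outcome_kind == "profile") {
    unclass(screen$outcomes)[idx, , drop = FALSE]
  } else {
    matrix(screen$outcomes[idx], ncol = 1L)
  }
  list(X = X, T = Tm, D = D, Y = Y, n = length(idx))
}

# loss + gradient of the full model on a batch (mean reduction over the
# batch for both heads). Exposed internally for optimizer steps and
# finite-difference checks.
codex_loss_grad <- function(model, X, Tm, D, Y, dropout = 0,
                            latent_noise = 0, want_grad = TRUE) {
  fw <- codex_apply(model, X, Tm, D, keep_cache = want_grad,
                    dropout = dropout, latent_noise = latent_noise)
  n <- nrow(X)
  if (model$config$head == "scalar") {
    r <- fw$out[, 1L] - Y[, 1L]
    loss <- mean(r^2)
    if (!want_grad) return(list(loss = loss))
    dOut <- matrix(2 * r / n, ncol = 1L)
  } else {
    p <- model$n_outcome
    mu <- fw$out[, seq_len(p), drop = FALSE]
    lv <- fw$out[, p + seq_len(p), drop = FALSE]
    eps <- model$config$variance_floor
    s2 <- exp(lv)
    log_s2 <- lv
    floored <- which(s2 < eps)   # floor rarely binds; patch in place
    if (length(floored)) {
      s2[floored] <- eps
      log_s2[floored] <- log(eps)
    }
    r <- mu - Y
    m <- n * p
    r2s <- r^2 / s2
    loss <- (0.5 * (sum(log_s2) + sum(r2s))) / m
    if (!want_grad) return(list(loss = loss))
    dmu <- r / s2 / m
    # variance path has zero gradient where the floor is active
    dlv <- 0.5 * (1 - r2s) / m
    if (length(floored)) dlv[floored] <- 0
    dOut <- cbind(dmu, dlv)
  }
  grads <- codex_backward(model, fw, dOut)
  list(loss = loss, grads = grads)
}

#' Train a model on a perturbation screen
#'
#' Minimizes the head-matching objective (mean squared error for the
#' scalar head, heteroscedastic Gaussian negative log likelihood for the
#' gaussian head) by minibatch Adam with decoupled weight decay. Only the
#' training-fold triplets are touched; a validation subset carved from
#' them drives early stopping, after which the best-epoch parameters are
#' restored. Fully reproducible under `cfg$seed`.
#'
#' @param model an untrained (or warm-start) [codex_model()].
#' @param screen a [perturb_screen()] whose outcome kind matches the head.
#' @param fold optional list with `train` (and ignored `test`) indices, as
#'   produced by [make_splits()]; default uses every triplet.
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `report` (per-epoch loss
#'   traces, best epoch, parameter checksum).
#' @export
train_codex <- function(model, screen, fold = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "codex_model"),
            inherits(screen, "perturb_screen"),
            inherits(cfg, "train_config"))
  expected <- if (model$config$head == "scalar") "scalar" else "profile"
  if (screen$outcome_kind != expected) {
    stop(sprintf("screen outcome kind '%s' does not match model head '%s'",
                 screen$outcome_kind, model$config$head), call. = FALSE)
  }
  idx <- if (is.null(fold)) seq_len(n_triplets(screen)) else fold$train

  withr::with_seed(cfg$seed, {
    n_val <- floor(cfg$val_fraction * length(idx))
    val_idx <- if (n_val > 0L) sample(idx, n_val) else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    tr <- screen_tensors(screen, tr_idx)
    va <- if (n_val > 0L) screen_tensors(screen, val_idx)

    theta <- codex_flatten(model)
    opt <- adam_init(length(theta))
    blocks <- codex_param_blocks(model)
    wd_vec <- rep(cfg$weight_decay, length(theta))
    mult <- cfg$decoder_mlp_decay_mult %||% 1
    if (mult != 1) {
      dec_idx <- blocks[["encoder"]] + blocks[["branches"]] +
        seq_len(blocks[["decoder"]])
      wd_vec[dec_idx] <- wd_vec[dec_idx] * mult
    }
    ema <- if (cfg$ema_decay > 0) theta
    best <- list(loss = Inf, theta = theta, epoch = 0L)
    train_trace <- val_trace <- numeric(0)
    wait <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(tr$n)
      starts <- seq(1L, tr$n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        b <- ord[s:min(s + cfg$batch_size - 1L, tr$n)]
        lg <- codex_loss_grad(model, tr$X[b, , drop = FALSE],
                              tr$T[b, , drop = FALSE],
                              if (!is.null(tr$D)) tr$D[b, , drop = FALSE],
                              tr$Y[b, , drop = FALSE],
                              dropout = model$config$dropout,
                              latent_noise = model$config$latent_noise %||% 0)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "training diverged at epoch %d (non-finite loss); lower the learning rate",
            epoch), call. = FALSE)
        }
        step <- adam_step(opt, theta, flatten_grads(lg$grads),
                          lr = cfg$learning_rate,
                          weight_decay = wd_vec)
        opt <- step$state
        theta <- step$theta
        if (!is.null(ema)) {
          ema <- cfg$ema_decay * ema + (1 - cfg$ema_decay) * theta
        }
        model <- codex_unflatten(model, theta)
        epoch_loss <- epoch_loss + lg$loss * length(b)
      }
      train_trace[epoch] <- epoch_loss / tr$n

      eval_theta <- if (!is.null(ema)) ema else theta
      eval_model <- if (!is.null(ema)) codex_unflatten(model, ema) else model
      monitor <- if (n_val > 0L) {
        val_trace[epoch] <- codex_loss_grad(eval_model, va$X, va$T, va$D,
                                            va$Y, want_grad = FALSE)$loss
        val_trace[epoch]
      } else {
        val_trace[epoch] <- NA_real_
        train_trace[epoch]
      }
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, theta = eval_theta, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    model <- codex_unflatten(model, best$theta)
  })

  report <- list(train_loss = train_trace, val_loss = val_trace,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 n_train = length(tr_idx), n_val = n_val,
                 checksum = sum(abs(best$theta)))
  class(report) <- "train_report"
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(
    "<train_report> %d epochs run, best epoch %d (monitored loss %.5g), %d/%d train/val triplets\n",
    length(x$train_loss), x$best_epoch, x$best_val_loss, x$n_train, x$n_val))
  invisible(x)
}
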