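# Simulation benchmarks: end-to-end experiments (simulate -> train ->
# evaluate) that probe the model's headline claims at desk scale. Problem
# sizes and generator settings are fixed study conditions, documented in
# the methods vignette; `seed` drives every random choice.

# mean predicted profile for the cells of one condition
predict_condition_mean <- function(model, screen, rows, t_row, dose_row = NULL) {
  X <- unclass(screen$controls)[screen$pairing[rows], , drop = FALSE]
  out <- codex_forward(model, X, t_row,
                       if (!is.null(dose_row)) dose_row)
  colMeans(out$mu)
}

# fixed-epoch schedule: in-distribution validation loss is uninformative
# about extrapolation to held-out combinations, so the benchmarks train
# for a fixed budget instead of early-stopping on it
benchmark_train_config <- function(seed) {
  train_config(epochs = 600L, batch_size = 256L, learning_rate = 1e-3,
               weight_decay = 1e-3, early_stop_patience = 100000L,
               val_fraction = 0.1, decoder_mlp_decay_mult = 10,
               ema_decay = 0.999, seed = seed)
}

#' Held-out combination benchmark
#'
#' Simulates a screen of 8 perturbations measured singly plus 12 pairs
#' with interaction strength `gamma`, holds 2 pairs out, trains the model
#' on the rest and evaluates the reconstruction of the held-out pairs'
#' mean profiles on the top 50 differentially expressed genes, against
#' the linear additivity baseline and the single-branch averaging
#' ablation. With `gamma = 0` the latent effects are exactly additive,
#' which is the null condition under which the full model and the
#' ablation should be indistinguishable.
#'
#' @param seed integer seed for the whole experiment.
#' @param gamma interaction strength of every measured pair.
#' @param n_genes,n_cells_per_condition screen size.
#' @param epochs training epochs (fixed budget, no early stopping).
#' @return `data.frame`, one row per held-out pair: top-50-DEG R^2 for
#'   the model (`r2_codex`), the linear baseline (`r2_linear`), the
#'   effect-sum ablation (`r2_lincodex`) and the averaging ablation
#'   (`r2_lincodex_avg`), plus effect PCCs.
#' @export
benchmark_combination <- function(seed, gamma = 2, n_genes = 200L,
                                  n_cells_per_condition = 200L,
                                  epochs = 450L) {
  K <- 8L
  n_pairs <- 12L
  all_pairs <- utils::combn(K, 2L)
  sel <- withr::with_seed(seed + 1000L, {
    pick <- sample(ncol(all_pairs), n_pairs)
    held <- sample(n_pairs, 2L)
    list(pairs = all_pairs[, pick, drop = FALSE], held = held)
  })
  pairs_df <- data.frame(k = sel$pairs[1L, ], l = sel$pairs[2L, ],
                         gamma = gamma)
  cfg <- synth_config(
    n_genes = n_genes, n_perturbations = K,
    n_cells_per_condition = n_cells_per_condition,
    interaction_pairs = pairs_df,
    conditions = c(list(integer(0)),            # measured control condition
                   lapply(seq_len(K), identity),
                   lapply(seq_len(nrow(pairs_df)), function(i) {
                     sort(c(pairs_df$k[i], pairs_df$l[i]))
                   })),
    seed = seed)
  sim <- simulate_screen(cfg)
  screen <- sim$screen

  sig <- combo_signature(screen$design)
  held_sigs <- vapply(sel$held, function(i) {
    paste(sort(sprintf("P%d", sel$pairs[, i])), collapse = "+")
  }, character(1))
  fold <- list(train = which(!sig %in% held_sigs),
               test = which(sig %in% held_sigs))

  mcfg <- benchmark_model_config(seed)
  model <- codex_model(mcfg, ncol(screen$controls),
                       screen$design$perturbation_ids,
                       n_outcome = ncol(screen$outcomes))
  tc <- benchmark_train_config(seed)
  tc$epochs <- as.integer(epochs)
  fit <- train_codex(model, screen, fold, tc)

  control_mean <- colMeans(unclass(screen$controls))
  res <- lapply(held_sigs, function(hs) {
    rows <- which(sig == hs)
    combo <- strsplit(hs, "+", fixed = TRUE)[[1L]]
    t_row <- as.numeric(screen$design$perturbation_ids %in% combo)
    truth_cells <- unclass(screen$outcomes)[rows, , drop = FALSE]
    pred <- predict_condition_mean(fit$model, screen, rows, t_row)
    X <- unclass(screen$controls)[screen$pairing[rows], , drop = FALSE]
    pred_lin <- linear_baseline(screen, combo)
    pred_abl_sum <- colMeans(lincodex_predict(fit$model, X, combo,
                                              mode = "effect_sum"))
    pred_abl_avg <- colMeans(lincodex_predict(fit$model, X, combo))
    ev <- function(p) eval_condition(p, truth_cells, control_mean, k = 50L)
    data.frame(combo = hs,
               r2_codex = ev(pred)$r2_topk,
               r2_linear = ev(pred_lin)$r2_topk,
               r2_lincodex = ev(pred_abl_sum)$r2_topk,
               r2_lincodex_avg = ev(pred_abl_avg)$r2_topk,
               pcc_effect_codex = ev(pred)$pcc_effect,
               pcc_effect_linear = ev(pred_lin)$pcc_effect)
  })
  do.call(rbind, res)
}

# architecture used by the simulation benchmarks: a small latent space,
# a narrow decoder with a residual linear path, dropout and latent noise.
# Tight decoder capacity is what makes extrapolation to unseen treatment
# combinations reliable; see the methods vignette.
benchmark_model_config <- function(seed, ...) {
  codex_config(latent_dim = 4L, encoder_widths = 64L,
               branch_widths = integer(0), decoder_widths = 8L,
               head = "gaussian", decoder_residual = TRUE,
               dropout = 0.1, latent_noise = 0.3, seed = seed, ...)
}

#' Dose-interpolation benchmark
#'
#' Simulates four singly applied perturbations with monotone Hill-curve
#' dose responses over seven log-spaced concentrations, holds out the
#' second-highest concentration, trains a dosed model on the remaining
#' six, and evaluates the reconstruction at the unseen concentration
#' (top-50-DEG R^2) against the control-centroid baseline.
#'
#' @param seed integer seed.
#' @param n_genes,n_cells_per_condition screen size.
#' @param epochs training epoch cap.
#' @return `data.frame`, one row per perturbation: `r2_codex`,
#'   `r2_control`, and the predicted vs true dose-response positioning.
#' @export
benchmark_dose_interpolation <- function(seed, n_genes = 150L,
                                         n_cells_per_condition = 150L,
                                         epochs = 400L) {
  K <- 4L
  doses <- 10^seq(-2, 1, length.out = 7L)
  cfg <- synth_config(
    n_genes = n_genes, n_perturbations = K,
    n_cells_per_condition = n_cells_per_condition,
    conditions = lapply(seq_len(K), identity),
    dose_levels = doses,
    seed = seed)
  sim <- simulate_screen(cfg)
  screen <- sim$screen
  held_dose <- doses[6L]

  dose_of_row <- apply(screen$design$dosages, 1L, max)
  fold <- list(train = which(dose_of_row != held_dose),
               test = which(dose_of_row == held_dose))
  train_doses <- sort(unique(dose_of_row[fold$train]))

  mcfg <- benchmark_model_config(seed, dose_transform = "log10_minmax")
  model <- codex_model(mcfg, ncol(screen$controls),
                       screen$design$perturbation_ids,
                       n_outcome = ncol(screen$outcomes),
                       dose_levels = train_doses)
  tc <- benchmark_train_config(seed)
  tc$epochs <- as.integer(epochs)
  fit <- train_codex(model, screen, fold, tc)

  control_mean <- colMeans(unclass(screen$controls))
  sig <- combo_signature(screen$design)
  res <- lapply(seq_len(K), function(k) {
    id <- sprintf("P%d", k)
    rows <- which(sig == id & dose_of_row == held_dose)
    t_row <- as.numeric(screen$design$perturbation_ids == id)
    d_row <- t_row * held_dose
    truth_cells <- unclass(screen$outcomes)[rows, , drop = FALSE]
    pred <- predict_condition_mean(fit$model, screen, rows, t_row, d_row)
    ev <- eval_condition(pred, truth_cells, control_mean, k = 50L)
    ev_ctrl <- eval_condition(control_mean, truth_cells, control_mean, k = 50L)
    # monotone-interpolation check: on the top-50 DEGs, the predicted
    # effect size at the held-out dose should lie between the model's
    # predictions at the two neighbouring training doses
    degs <- top_k_degs(colMeans(truth_cells), control_mean, 50L)
    eff_at <- function(d) {
      p <- predict_condition_mean(fit$model, screen, rows, t_row, t_row * d)
      sqrt(mean((p[degs] - control_mean[degs])^2))
    }
    eff <- vapply(doses[5:7], eff_at, numeric(1))
    tol <- 0.05 * max(eff)
    data.frame(perturbation = id, held_dose = held_dose,
               r2_codex = ev$r2_topk, r2_control = ev_ctrl$r2_topk,
               pcc_effect_codex = ev$pcc_effect,
               between_neighbors = eff[2L] >= min(eff[c(1L, 3L)]) - tol &
                 eff[2L] <= max(eff[c(1L, 3L)]) + tol)
  })
  do.call(rbind, res)
}

#' Unseen-perturbation proxy benchmark
#'
#' Simulates eight singly observed perturbations organized in four
#' pathway blocks of two, holds one perturbation out entirely (0-of-1
#' seen), trains on the remaining seven, derives the gene-set annotation
#' from the simulation truth and predicts the held-out perturbation via
#' its Jaccard proxy vector. Reports the Pearson correlation of the
#' predicted effect (profile minus control mean) with the true effect,
#' against the control-centroid baseline whose effect is identically zero
#' (its undefined correlation is scored 0).
#'
#' @param seed integer seed.
#' @param n_genes,n_cells_per_condition screen size.
#' @param epochs training epoch cap.
#' @return one-row `data.frame` with `target`, `pcc_effect_proxy`,
#'   `pcc_effect_control` and the proxy weight on the same-block partner.
#' @export
benchmark_proxy_recovery <- function(seed, n_genes = 150L,
                                     n_cells_per_condition = 150L,
                                     epochs = 400L) {
  K <- 8L
  blocks <- list(1:2, 3:4, 5:6, 7:8)
  cfg <- synth_config(
    n_genes = n_genes, n_perturbations = K,
    n_cells_per_condition = n_cells_per_condition,
    conditions = c(list(integer(0)), lapply(seq_len(K), identity)),
    pathway_blocks = blocks,
    seed = seed)
  sim <- simulate_screen(cfg)
  screen <- sim$screen
  target_k <- withr::with_seed(seed + 2000L, sample.int(K, 1L))
  target <- sprintf("P%d", target_k)
  observed <- setdiff(screen$design$perturbation_ids, target)

  sig <- combo_signature(screen$design)
  fold <- list(train = which(sig != target), test = which(sig == target))

  mcfg <- benchmark_model_config(seed)
  model <- codex_model(mcfg, ncol(screen$controls),
                       screen$design$perturbation_ids,
                       n_outcome = ncol(screen$outcomes))
  tc <- benchmark_train_config(seed)
  tc$epochs <- as.integer(epochs)
  fit <- train_codex(model, screen, fold, tc)

  ann <- gmt_from_truth(sim$truth)
  proxy <- build_proxy(target, observed, ann)
  t_full <- stats::setNames(numeric(K), screen$design$perturbation_ids)
  t_full[observed] <- proxy$weights
  t_eff <- effective_treatment(
    stats::setNames(numeric(K), screen$design$perturbation_ids),
    list(stats::setNames(t_full, NULL)))

  control_mean <- colMeans(unclass(screen$controls))
  rows <- fold$test
  truth_cells <- unclass(screen$outcomes)[rows, , drop = FALSE]
  pred <- predict_condition_mean(fit$model, screen, rows, t_eff)
  ev <- eval_condition(pred, truth_cells, control_mean, k = 50L)
  partner <- setdiff(sprintf("P%d", blocks[[ceiling(target_k / 2)]]), target)
  data.frame(target = target,
             pcc_effect_proxy = ev$pcc_effect,
             # the centroid predicts a zero effect: correlation undefined,
             # scored as 0 information
             pcc_effect_control = 0,
             r2_topk_proxy = ev$r2_topk,
             partner_weight = proxy$weights[[partner]])
}
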