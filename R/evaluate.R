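# Baselines and evaluation metrics.

# set of active perturbation ids of each design row, as a canonical string
combo_signature <- function(design) {
  apply(design$matrix, 1L, function(r) {
    paste(sort(design$perturbation_ids[r != 0]), collapse = "+")
  })
}

# rows of `screen` that are exactly the single perturbation `id`
single_rows <- function(screen, id) {
  which(combo_signature(screen$design) == id)
}

#' Linear additivity baseline
#'
#' Predicts the outcome of a perturbation combination as the arithmetic
#' mean of the mean post-perturbation profiles of its individually
#' observed members.
#'
#' @param screen a profile-outcome [perturb_screen()] (training data).
#' @param combo character vector of perturbation ids.
#' @return predicted profile vector.
#' @export
linear_baseline <- function(screen, combo) {
  stopifnot(screen$outcome_kind == "profile")
  profs <- lapply(combo, function(id) {
    rows <- single_rows(screen, id)
    if (length(rows) == 0L) {
      stop("no single-perturbation observations for: ", id, call. = FALSE)
    }
    colMeans(unclass(screen$outcomes)[rows, , drop = FALSE])
  })
  Reduce(`+`, profs) / length(profs)
}

#' Single-branch ablation (lin-CODEX)
#'
#' Evaluates the trained model once per combination member with a one-hot
#' treatment vector and combines the predictions in outcome space,
#' removing the decoder's nonlinear combination of effects. Two
#' composition rules are offered: `"average"` takes the arithmetic mean
#' of the single-branch predictions; `"effect_sum"` adds up the
#' single-branch *effects* relative to the model's control-state
#' prediction (`sum_k d(f_k) - (m - 1) * d(0)` for m members), which is
#' the purely additive composition -- for an affine decoder it coincides
#' exactly with the full forward pass, so it isolates the decoder's
#' nonlinearity.
#'
#' @param model a trained [codex_model()].
#' @param x control profile vector (or matrix of profiles).
#' @param combo character vector (or indices) of perturbation ids.
#' @param doses optional named vector of raw doses for the members.
#' @param mode `"average"` (default) or `"effect_sum"`.
#' @return scalar-head: numeric; gaussian-head: the combined `mu` matrix.
#' @export
lincodex_predict <- function(model, x, combo, doses = NULL,
                             mode = c("average", "effect_sum")) {
  mode <- match.arg(mode)
  if (length(combo) == 0L) stop("empty combination", call. = FALSE)
  K <- length(model$perturbation_ids)
  preds <- lapply(combo, function(id) {
    k <- if (is.character(id)) match(id, model$perturbation_ids) else id
    if (is.na(k)) stop("unknown perturbation: ", id, call. = FALSE)
    t1 <- numeric(K)
    t1[k] <- 1
    d1 <- NULL
    if (!is.null(doses)) {
      d1 <- numeric(K)
      d1[k] <- if (!is.null(names(doses))) doses[[as.character(id)]] else
        doses[match(id, combo)]
    }
    out <- codex_forward(model, x, t1, d1)
    if (model$config$head == "gaussian") out$mu else out
  })
  if (mode == "average") {
    Reduce(`+`, preds) / length(preds)
  } else {
    ctrl <- codex_forward(model, x, numeric(K))
    if (model$config$head == "gaussian") ctrl <- ctrl$mu
    Reduce(`+`, preds) - (length(preds) - 1) * ctrl
  }
}

#' Random (control-centroid) baseline
#'
#' The reference prediction used to normalize reconstruction errors:
#' either the control centroid (default) or a seed-drawn training outcome
#' profile.
#'
#' @param screen a profile-outcome [perturb_screen()].
#' @param seed integer seed (used by the sampled strategy).
#' @param strategy `"control_centroid"` or `"sampled"`.
#' @return profile vector.
#' @export
random_baseline <- function(screen, seed = 1L,
                            strategy = c("control_centroid", "sampled")) {
  strategy <- match.arg(strategy)
  if (strategy == "control_centroid") {
    colMeans(unclass(screen$controls))
  } else {
    i <- withr::with_seed(seed, sample.int(n_triplets(screen), 1L))
    unclass(screen$outcomes)[i, ]
  }
}

#' Top differentially expressed genes
#'
#' Indices of the `k` genes with the largest absolute difference between
#' the mean perturbed and the mean control profile; ties are broken by
#' input order.
#'
#' @param perturbed_mean,control_mean profile vectors.
#' @param k number of genes.
#' @return integer vector of gene indices (in decreasing effect order).
#' @export
top_k_degs <- function(perturbed_mean, control_mean, k) {
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a positive count", call. = FALSE)
  }
  d <- abs(as.numeric(perturbed_mean) - as.numeric(control_mean))
  if (k > length(d)) stop("k exceeds the number of genes", call. = FALSE)
  order(-d, seq_along(d))[seq_len(k)]
}

r_squared <- function(pred, truth) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((pred - truth)^2) / ss_tot
}

safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Evaluate a predicted condition
#'
#' Compares a predicted profile against the mean observed profile of a
#' held-out condition. Reports R^2, Pearson and Spearman correlation on
#' all genes and on the top-`k` differentially expressed genes, the
#' Pearson correlation of the *effect* (profile minus control mean, i.e.
#' ignoring the control background), the MSE, and the MSE on the top-`k`
#' genes normalized by the same error of the reference baseline.
#' Correlations of zero-variance vectors are reported as `NA`.
#'
#' @param pred predicted profile vector (for a gaussian head, the `mu`).
#' @param truth matrix of observed cells for the condition (cells x
#'   genes), or a single profile vector.
#' @param control_mean control centroid profile.
#' @param k DEG count (default 50).
#' @param baseline reference prediction for the normalized MSE; defaults
#'   to `control_mean`.
#' @return one-row `data.frame` of metrics.
#' @export
eval_condition <- function(pred, truth, control_mean, k = 50L,
                           baseline = control_mean) {
  truth <- if (is.matrix(truth)) truth else matrix(truth, nrow = 1L)
  tm <- colMeans(truth)
  pred <- as.numeric(pred)
  control_mean <- as.numeric(control_mean)
  baseline <- as.numeric(baseline)
  degs <- top_k_degs(tm, control_mean, min(k, length(tm)))
  mse_base <- mean((baseline[degs] - tm[degs])^2)
  data.frame(
    r2_all = r_squared(pred, tm),
    r2_topk = r_squared(pred[degs], tm[degs]),
    pcc_all = safe_cor(pred, tm),
    scc_all = safe_cor(pred, tm, method = "spearman"),
    pcc_topk = safe_cor(pred[degs], tm[degs]),
    pcc_effect = safe_cor(pred - control_mean, tm - control_mean),
    mse_all = mean((pred - tm)^2),
    nmse_topk = if (mse_base == 0) NA_real_ else
      mean((pred[degs] - tm[degs])^2) / mse_base,
    k = length(degs))
}
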