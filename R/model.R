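#' Model configuration
#'
#' Architecture and numerical settings for the counterfactual perturbation
#' model: a shared encoder mapping the unperturbed profile to a latent
#' state of dimension `latent_dim`, one branch network per intervention
#' (latent to latent, optionally taking a transformed dosage as an extra
#' input to its first layer), and a shared decoder head.
#'
#' @param latent_dim latent dimension d of the shared embedding.
#' @param encoder_widths,branch_widths,decoder_widths hidden-layer sizes;
#'   an empty vector means a single affine layer.
#' @param activation hidden activation; only `"elu"` is implemented.
#' @param head `"gaussian"` for heteroscedastic transcriptome prediction
#'   (per-gene mean and variance), `"scalar"` for synergy-score regression.
#' @param variance_floor lower bound applied to every decoded variance,
#'   `max(sigma2, variance_floor)`, for numerical stability.
#' @param dose_transform `"none"` (undosed model), `"log10_minmax"`
#'   (log10 dose rescaled to \[0, 1\] over the training doses; the sentinel
#'   "no dose" maps to 0, coinciding with the lowest training dose), or
#'   `"categorical"` (one-hot over the training dose levels).
#' @param dropout dropout rate on hidden activations during training.
#' @param decoder_residual add a direct linear path from the latent
#'   effect to the decoder output alongside the nonlinear stack
#'   (`out = A z + b + MLP(z)`). The linear path composes additively
#'   across branches, so extrapolation to unseen treatment combinations
#'   degrades gracefully to the additive prediction while the nonlinear
#'   stack captures interaction corrections. Default on.
#' @param latent_noise standard deviation of Gaussian noise added to the
#'   aggregated latent effect during training; smooths the decoder around
#'   observed treatment combinations and improves extrapolation to unseen
#'   ones. Inactive at prediction time.
#' @param seed seed for parameter initialization.
#' @return A `codex_config` list.
#' @export
codex_config <- function(latent_dim = 32L,
                         encoder_widths = 64L,
                         branch_widths = integer(0),
                         decoder_widths = 64L,
                         activation = "elu",
                         head = c("gaussian", "scalar"),
                         variance_floor = 1e-6,
                         dose_transform = c("none", "log10_minmax",
                                            "categorical"),
                         dropout = 0,
                         decoder_residual = TRUE,
                         latent_noise = 0,
                         seed = 1L) {
  head <- match.arg(head)
  dose_transform <- match.arg(dose_transform)
  activation <- match.arg(activation, "elu")
  stopifnot(latent_dim >= 1L, variance_floor > 0,
            dropout >= 0, dropout < 1, latent_noise >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 branch_widths = as.integer(branch_widths),
                 decoder_widths = as.integer(decoder_widths),
                 activation = activation, head = head,
                 variance_floor = variance_floor,
                 dose_transform = dose_transform,
                 dropout = dropout, latent_noise = latent_noise,
                 decoder_residual = isTRUE(decoder_residual),
                 seed = as.integer(seed)),
            class = "codex_config")
}

# number of extra branch inputs carrying the dose
dose_input_dim <- function(model) {
  switch(model$config$dose_transform,
         none = 0L,
         log10_minmax = 1L,
         categorical = length(model$dose_levels))
}

#' Build an untrained model
#'
#' Allocates the parameter container: encoder parameters, one branch
#' parameter set per perturbation, and decoder parameters, initialized
#' with fan-in scaled Gaussian weights under `config$seed`.
#'
#' @param config a [codex_config()].
#' @param n_genes_in input dimension (genes of the control profile).
#' @param perturbation_ids names of the K interventions (branch order).
#' @param n_outcome output dimension: genes of the perturbed profile
#'   (gaussian head) or ignored for the scalar head.
#' @param dose_levels training dose levels; required when
#'   `dose_transform != "none"` (they fix the dose rescaling/encoding).
#' @return A `codex_model`.
#' @export
codex_model <- function(config, n_genes_in, perturbation_ids,
                        n_outcome = n_genes_in, dose_levels = NULL) {
  stopifnot(inherits(config, "codex_config"))
  perturbation_ids <- as.character(perturbation_ids)
  K <- length(perturbation_ids)
  if (K < 1L) stop("at least one perturbation is required", call. = FALSE)
  if (anyDuplicated(perturbation_ids)) {
    stop("perturbation_ids must be unique", call. = FALSE)
  }
  model <- structure(list(config = config,
                          perturbation_ids = perturbation_ids,
                          n_input = as.integer(n_genes_in),
                          n_outcome = as.integer(n_outcome),
                          dose_levels = NULL),
                     class = "codex_model")
  if (config$dose_transform != "none") {
    if (is.null(dose_levels) || length(dose_levels) < 1L) {
      stop("dose_levels required for a dosed model", call. = FALSE)
    }
    if (any(dose_levels <= 0)) {
      stop("dose_levels must be positive", call. = FALSE)
    }
    model$dose_levels <- sort(unique(as.numeric(dose_levels)))
  }
  d <- config$latent_dim
  out_dim <- if (config$head == "scalar") 1L else 2L * model$n_outcome
  model$encoder <- NULL
  withr::with_seed(config$seed, {
    model$encoder <- mlp_new(c(model$n_input, config$encoder_widths, d))
    model$branches <- lapply(seq_len(K), function(k) {
      mlp_new(c(d + dose_input_dim(model), config$branch_widths, d))
    })
    model$decoder <- mlp_new(c(d, config$decoder_widths, out_dim))
    if (isTRUE(config$decoder_residual)) {
      model$decoder_linear <- mlp_new(c(d, out_dim))[[1L]]
    }
  })
  # damp the output layer so initial predictions sit near zero mean and
  # unit variance (log-variance 0); keeps the first Gaussian-loss steps
  # away from the variance floor
  L <- length(model$decoder)
  model$decoder[[L]]$W <- model$decoder[[L]]$W * 0.01
  if (!is.null(model$decoder_linear)) {
    model$decoder_linear$W <- model$decoder_linear$W * 0.01
  }
  names(model$branches) <- perturbation_ids
  model
}

#' @export
print.codex_model <- function(x, ...) {
  cat(sprintf(
    "<codex_model> %d genes -> latent %d -> %s head (%d outputs), %d branches%s\n",
    x$n_input, x$config$latent_dim, x$config$head, x$n_outcome,
    length(x$perturbation_ids),
    if (x$config$dose_transform == "none") "" else
      sprintf(", dosed (%s)", x$config$dose_transform)))
  invisible(x)
}

# map raw doses to branch input features; d may contain the 0 sentinel
dose_features <- function(model, d) {
  tf <- model$config$dose_transform
  if (tf == "none") return(NULL)
  d <- as.numeric(d)
  if (tf == "log10_minmax") {
    rng <- log10(range(model$dose_levels))
    f <- numeric(length(d))
    pos <- d > 0
    if (diff(rng) > 0) {
      f[pos] <- (log10(d[pos]) - rng[1L]) / diff(rng)
    }
    matrix(f, ncol = 1L)
  } else {
    F <- matrix(0, length(d), length(model$dose_levels))
    pos <- which(d > 0)
    idx <- match(d[pos], model$dose_levels)
    if (anyNA(idx)) {
      stop("categorical dose encoding: dose not among training levels",
           call. = FALSE)
    }
    F[cbind(pos, idx)] <- 1
    F
  }
}

#' Encode unperturbed profiles
#'
#' Applies the shared encoder to one profile (vector) or a batch (matrix,
#' samples in rows), returning the latent state(s). Deterministic: dropout
#' is a training-time device only.
#'
#' @param model a [codex_model()].
#' @param x numeric vector of length `n_input`, or a samples x `n_input`
#'   matrix.
#' @return latent matrix (samples x `latent_dim`); a single profile gives
#'   one row.
#' @export
encode <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != model$n_input) {
    stop(sprintf("profile length %d does not match model input %d",
                 ncol(X), model$n_input), call. = FALSE)
  }
  mlp_forward(model$encoder, X)$out
}

#' Apply one intervention branch
#'
#' Maps latent states through the branch of perturbation `k`. For dosed
#' models the transformed dose enters the first branch layer as an extra
#' input feature; by convention the "no dose" sentinel and the reference
#' (lowest training) dose are encoded identically.
#'
#' @param model a [codex_model()].
#' @param h latent vector or matrix (rows = samples).
#' @param k perturbation index or id.
#' @param dose raw dose (scalar or per-row vector); only for dosed models.
#' @return latent matrix of the same row count.
#' @export
branch_apply <- function(model, h, k, dose = NULL) {
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1L)
  if (ncol(H) != model$config$latent_dim) {
    stop("latent input has wrong dimension", call. = FALSE)
  }
  if (is.character(k)) k <- match(k, model$perturbation_ids)
  if (is.na(k) || k < 1L || k > length(model$branches)) {
    stop("invalid perturbation index", call. = FALSE)
  }
  if (model$config$dose_transform == "none") {
    if (!is.null(dose)) {
      stop("dose supplied to an undosed model", call. = FALSE)
    }
  } else {
    if (is.null(dose)) dose <- 0
    H <- cbind(H, dose_features(model, rep_len(dose, nrow(H))))
  }
  mlp_forward(model$branches[[k]], H)$out
}

#' Aggregate branch outputs
#'
#' The latent effect is the weighted sum of the active branch outputs,
#' z = sum_j w_j f_j(e(x)); branches with zero weight need not be supplied
#' (they are never evaluated). An all-zero weight row yields the zero
#' vector (empty-sum convention), so decoding it gives the model's
#' control-state prediction.
#'
#' @param branch_outputs named list (by perturbation id) or list indexed
#'   like the nonzero weights, each a latent row matrix/vector.
#' @param weights numeric length-K weight vector (an effective treatment
#'   row); names, if present, select entries from `branch_outputs`.
#' @param latent_dim latent dimension, needed only for the all-zero case
#'   when `branch_outputs` is empty.
#' @return latent vector (or matrix) z.
#' @export
aggregate_branches <- function(branch_outputs, weights, latent_dim = NULL) {
  active <- which(weights != 0)
  if (length(active) == 0L) {
    if (length(branch_outputs)) {
      proto <- branch_outputs[[1L]]
      return(matrix(0, nrow(as.matrix(proto)),
                    if (is.matrix(proto)) ncol(proto) else length(proto)))
    }
    if (is.null(latent_dim)) {
      stop("latent_dim needed to build the zero latent effect", call. = FALSE)
    }
    return(matrix(0, 1L, latent_dim))
  }
  keys <- if (!is.null(names(weights))) names(weights)[active] else
    as.character(seq_along(active))
  z <- NULL
  for (i in seq_along(active)) {
    out <- branch_outputs[[keys[i]]]
    out <- if (is.matrix(out)) out else matrix(out, nrow = 1L)
    term <- weights[active[i]] * out
    z <- if (is.null(z)) term else z + term
  }
  z
}

# decoder forward shared by both heads (includes the residual linear
# path when configured)
decode_raw <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(Z) != model$config$latent_dim) {
    stop("latent effect has wrong dimension", call. = FALSE)
  }
  out <- mlp_forward(model$decoder, Z)$out
  if (!is.null(model$decoder_linear)) {
    out <- add_bias(out + Z %*% model$decoder_linear$W,
                    model$decoder_linear$b)
  }
  out
}

#' Decode a latent effect to a scalar outcome
#'
#' @param model a [codex_model()] with `head = "scalar"`.
#' @param z latent effect vector or matrix.
#' @return numeric vector of predicted outcomes (one per row of `z`).
#' @export
decode_scalar <- function(model, z) {
  if (model$config$head != "scalar") {
    stop("decode_scalar requires a scalar-head model", call. = FALSE)
  }
  drop(decode_raw(model, z)[, 1L])
}

#' Decode a latent effect to a heteroscedastic Gaussian prediction
#'
#' The decoder's output parameterizes, per gene, a mean and a log
#' variance; variances are exponentiated and floored at
#' `config$variance_floor` so every returned variance is strictly
#' positive.
#'
#' @param model a [codex_model()] with `head = "gaussian"`.
#' @param z latent effect vector or matrix.
#' @return list with `mu` and `sigma2`, each samples x genes.
#' @export
decode_gaussian <- function(model, z) {
  if (model$config$head != "gaussian") {
    stop("decode_gaussian requires a gaussian-head model", call. = FALSE)
  }
  out <- decode_raw(model, z)
  p <- model$n_outcome
  mu <- out[, seq_len(p), drop = FALSE]
  sigma2 <- pmax(exp(out[, p + seq_len(p), drop = FALSE]),
                 model$config$variance_floor)
  list(mu = mu, sigma2 = sigma2)
}

#' Full forward pass
#'
#' Composes encoder, the branches with nonzero weight (zero-weight
#' branches are skipped; the result provably equals evaluating every
#' branch and weighting), aggregation and the decoder head. Accepts
#' multi-hot observed rows as well as fractional proxy-augmented rows.
#'
#' @param model a [codex_model()].
#' @param x control profile vector, or samples x genes matrix.
#' @param t effective treatment weight vector (length K), or a samples x K
#'   matrix aligned with the rows of `x`.
#' @param dose raw dose vector (length K) or samples x K matrix; dosed
#'   models only.
#' @return scalar-head: numeric vector; gaussian-head: list(mu, sigma2).
#' @export
codex_forward <- function(model, x, t, dose = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  K <- length(model$perturbation_ids)
  Tm <- if (is.matrix(t)) t else matrix(t, nrow = 1L)
  if (ncol(Tm) != K) stop("treatment row length must be K", call. = FALSE)
  if (nrow(Tm) == 1L && nrow(X) > 1L) {
    Tm <- Tm[rep(1L, nrow(X)), , drop = FALSE]
  }
  if (nrow(Tm) != nrow(X)) {
    stop("treatment rows do not match profiles", call. = FALSE)
  }
  D <- NULL
  if (!is.null(dose)) {
    if (model$config$dose_transform == "none") {
      stop("dose supplied to an undosed model", call. = FALSE)
    }
    D <- if (is.matrix(dose)) dose else matrix(dose, nrow = 1L)
    if (nrow(D) == 1L && nrow(X) > 1L) D <- D[rep(1L, nrow(X)), , drop = FALSE]
  }
  fw <- codex_apply(model, X, Tm, D)
  if (model$config$head == "scalar") {
    drop(fw$out[, 1L])
  } else {
    p <- model$n_outcome
    list(mu = fw$out[, seq_len(p), drop = FALSE],
         sigma2 = pmax(exp(fw$out[, p + seq_len(p), drop = FALSE]),
                       model$config$variance_floor))
  }
}

# Batched core used by forward, prediction and training. Evaluates each
# branch only on the rows where its weight is nonzero. Returns the raw
# decoder output plus (optionally) every cache needed for backprop.
# `dropout > 0` draws inverted-dropout masks on hidden activations and
# `latent_noise > 0` perturbs the aggregated latent effect, both from the
# current RNG stream (training only).
codex_apply <- function(model, X, Tm, D = NULL, keep_cache = FALSE,
                        dropout = 0, latent_noise = 0) {
  masks_for <- function(layers, n) {
    if (dropout <= 0 || length(layers) < 2L) return(NULL)
    lapply(layers[-length(layers)], function(l) {
      keep <- 1 - dropout
      matrix((stats::runif(n * ncol(l$W)) < keep) / keep, n, ncol(l$W))
    })
  }
  enc_cache <- mlp_forward(model$encoder, X,
                           dropout_masks = masks_for(model$encoder, nrow(X)))
  H <- enc_cache$out
  n <- nrow(X)
  d <- model$config$latent_dim
  Z <- matrix(0, n, d)
  K <- length(model$perturbation_ids)
  branch_caches <- if (keep_cache) vector("list", K) else NULL
  branch_rows <- if (keep_cache) vector("list", K) else NULL
  for (k in seq_len(K)) {
    rows <- which(Tm[, k] != 0)
    if (length(rows) == 0L) next
    Hin <- H[rows, , drop = FALSE]
    if (model$config$dose_transform != "none") {
      dk <- if (is.null(D)) rep(0, length(rows)) else D[rows, k]
      Hin <- cbind(Hin, dose_features(model, dk))
    }
    bc <- mlp_forward(model$branches[[k]], Hin,
                      dropout_masks = masks_for(model$branches[[k]],
                                                length(rows)))
    Z[rows, ] <- Z[rows, , drop = FALSE] + Tm[rows, k] * bc$out
    if (keep_cache) {
      branch_caches[[k]] <- bc
      branch_rows[[k]] <- rows
    }
  }
  if (latent_noise > 0) {
    # identity gradient: backprop through the addition is unchanged
    Z <- Z + matrix(stats::rnorm(n * d, sd = latent_noise), n, d)
  }
  dec_cache <- mlp_forward(model$decoder, Z,
                           dropout_masks = masks_for(model$decoder, n))
  out <- dec_cache$out
  if (!is.null(model$decoder_linear)) {
    out <- add_bias(out + Z %*% model$decoder_linear$W,
                    model$decoder_linear$b)
  }
  res <- list(out = out, z = Z, z_decoded = Z)
  if (keep_cache) {
    res$enc_cache <- enc_cache
    res$dec_cache <- dec_cache
    res$branch_caches <- branch_caches
    res$branch_rows <- branch_rows
    res$Tm <- Tm
  }
  res
}

# Backward through the full composition; dOut is dLoss/d(decoder output).
# Returns gradients shaped like the model's parameter lists.
codex_backward <- function(model, fw, dOut) {
  dec_b <- mlp_backward(model$decoder, fw$dec_cache, dOut)
  dZ <- dec_b$dX
  dlin <- NULL
  if (!is.null(model$decoder_linear)) {
    dlin <- list(dW = crossprod(fw$z_decoded, dOut), db = colSums(dOut))
    dZ <- dZ + tcrossprod(dOut, model$decoder_linear$W)
  }
  n <- nrow(dZ)
  d <- model$config$latent_dim
  dH <- matrix(0, n, d)
  K <- length(model$perturbation_ids)
  branch_grads <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- fw$branch_rows[[k]]
    if (is.null(rows) || length(rows) == 0L) {
      branch_grads[[k]] <- zero_grads(model$branches[[k]])
      next
    }
    dBk <- fw$Tm[rows, k] * dZ[rows, , drop = FALSE]
    bb <- mlp_backward(model$branches[[k]], fw$branch_caches[[k]], dBk)
    dH[rows, ] <- dH[rows, , drop = FALSE] + bb$dX[, seq_len(d), drop = FALSE]
    branch_grads[[k]] <- list(dW = bb$dW, db = bb$db)
  }
  enc_b <- mlp_backward(model$encoder, fw$enc_cache, dH)
  list(encoder = list(dW = enc_b$dW, db = enc_b$db),
       branches = branch_grads,
       decoder = list(dW = dec_b$dW, db = dec_b$db),
       decoder_linear = dlin)
}

zero_grads <- function(layers) {
  list(dW = lapply(layers, function(l) l$W * 0),
       db = lapply(layers, function(l) l$b * 0))
}

# --- parameter (un)flattening for optimizers and gradient checks ---------

flatten_net <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

codex_flatten <- function(model) {
  c(flatten_net(model$encoder),
    unlist(lapply(model$branches, flatten_net), use.names = FALSE),
    flatten_net(model$decoder),
    if (!is.null(model$decoder_linear))
      c(as.numeric(model$decoder_linear$W), model$decoder_linear$b))
}

unflatten_net <- function(layers, theta, pos) {
  for (l in seq_along(layers)) {
    nw <- length(layers[[l]]$W)
    layers[[l]]$W[] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(layers[[l]]$b)
    layers[[l]]$b[] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  list(layers = layers, pos = pos)
}

codex_unflatten <- function(model, theta) {
  r <- unflatten_net(model$encoder, theta, 0L)
  model$encoder <- r$layers
  pos <- r$pos
  for (k in seq_along(model$branches)) {
    r <- unflatten_net(model$branches[[k]], theta, pos)
    model$branches[[k]] <- r$layers
    pos <- r$pos
  }
  r <- unflatten_net(model$decoder, theta, pos)
  model$decoder <- r$layers
  pos <- r$pos
  if (!is.null(model$decoder_linear)) {
    r <- unflatten_net(list(model$decoder_linear), theta, pos)
    model$decoder_linear <- r$layers[[1L]]
    pos <- r$pos
  }
  stopifnot(pos == length(theta))
  model
}

# per-parameter block lengths, in flatten order
codex_param_blocks <- function(model) {
  c(encoder = length(flatten_net(model$encoder)),
    branches = sum(vapply(model$branches, function(b)
      length(flatten_net(b)), numeric(1))),
    decoder = length(flatten_net(model$decoder)),
    decoder_linear = if (!is.null(model$decoder_linear))
      length(model$decoder_linear$W) + length(model$decoder_linear$b)
    else 0L)
}

flatten_grads <- function(grads) {
  fl <- function(g) unlist(Map(function(w, b) c(as.numeric(w), b),
                               g$dW, g$db), use.names = FALSE)
  c(fl(grads$encoder),
    unlist(lapply(grads$branches, fl), use.names = FALSE),
    fl(grads$decoder),
    if (!is.null(grads$decoder_linear))
      c(as.numeric(grads$decoder_linear$dW), grads$decoder_linear$db))
}

# --- serialization --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding a versioned list: schema
#' version, config, perturbation ids, dose levels and all parameter
#' tensors.
#'
#' @param model a [codex_model()].
#' @param path file path.
#' @return `load_codex` returns the model; `save_codex` its path,
#'   invisibly.
#' @export
save_codex <- function(model, path) {
  stopifnot(inherits(model, "codex_model"))
  obj <- list(schema = 1L, model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_codex
#' @export
load_codex <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, 1L)) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  structure(obj$model, class = "codex_model")
}
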