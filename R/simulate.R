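# Ground-truth simulator of perturbation screens. Controls follow a
# latent-factor model; perturbation k shifts the latent state by
# delta_k * hill(dose); a combination (k, l) additionally adds
# gamma_kl * (delta_k (.) delta_l) (Hadamard product) before an
# elementwise softplus maps latent to log-scale expression, and gene-wise
# Gaussian observation noise is added. gamma = 0 everywhere makes latent
# effects exactly additive; the Hadamard interaction is invisible to any
# purely additive model, which is what gives the ablation baselines a
# discriminative test.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

hill_response <- function(dose, ec50, slope) {
  ifelse(dose > 0, 1 / (1 + (ec50 / dose)^slope), 0)
}

#' Simulation configuration
#'
#' Defines a synthetic perturbation screen with known ground truth. All
#' randomness (ground-truth parameters, cells, noise, pairing) flows from
#' `seed` through one generator stream, so a configuration reproduces its
#' screen exactly.
#'
#' @param n_genes number of genes p.
#' @param n_latent_true dimension q of the true latent factors.
#' @param n_perturbations number K of perturbations.
#' @param n_cells_per_condition cells measured per condition.
#' @param n_controls control cells (default: one condition's worth).
#' @param effect_scale standard deviation of each perturbation's latent
#'   shift entries (log-expression units of per-gene effect).
#' @param interaction_pairs `data.frame(k, l, gamma)`: pairs measured in
#'   combination and their interaction strength; `gamma = 0` rows are
#'   measured but purely additive.
#' @param conditions list of integer vectors (perturbation index sets) to
#'   measure; an empty vector denotes the measured control condition
#'   (no intervention). Default: all singles plus the
#'   `interaction_pairs` pairs.
#' @param dose_levels optional vector of positive doses; when set, every
#'   condition is measured at each dose and latent shifts are scaled by a
#'   per-perturbation Hill curve (EC50 log-uniform over the dose range,
#'   slope uniform on \[1, 3\]).
#' @param noise_sd gene-wise observation noise; a scalar, a length-p
#'   vector, or `NULL` for the default uniform \[0.2, 0.5\] draw.
#' @param pathway_blocks optional list of integer vectors partitioning
#'   perturbations into pathway blocks; within a block, latent shifts
#'   share a common component, so pathway membership is correlated with
#'   effect similarity.
#' @param block_within_sd within-block deviation of latent shifts,
#'   relative to `effect_scale`.
#' @param baseline_mean,baseline_sd distribution of gene baselines on the
#'   pre-nonlinearity scale (around 3, softplus is close to linear, so
#'   additive latent effects stay near-additive in expression space).
#' @param cell_latent_sd cell-to-cell latent variability.
#' @param n_cell_lines,n_replicates,synergy_noise_sd scalar-outcome screen
#'   settings (see [simulate_synergy_screen()]).
#' @param seed integer master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 200L, n_latent_true = 6L,
                         n_perturbations = 8L,
                         n_cells_per_condition = 200L,
                         n_controls = n_cells_per_condition,
                         effect_scale = 0.5,
                         interaction_pairs = NULL,
                         conditions = NULL,
                         dose_levels = NULL,
                         noise_sd = NULL,
                         pathway_blocks = NULL,
                         block_within_sd = 0.3,
                         baseline_mean = 3, baseline_sd = 1,
                         cell_latent_sd = 0.4,
                         n_cell_lines = 20L, n_replicates = 1L,
                         synergy_noise_sd = 1,
                         seed = 1L) {
  stopifnot(n_genes >= 1L, n_latent_true >= 1L, n_perturbations >= 1L,
            n_cells_per_condition >= 1L, effect_scale >= 0,
            baseline_sd >= 0, cell_latent_sd >= 0)
  if (!is.null(interaction_pairs)) {
    stopifnot(is.data.frame(interaction_pairs),
              all(c("k", "l", "gamma") %in% names(interaction_pairs)),
              all(interaction_pairs$k != interaction_pairs$l),
              all(is.finite(interaction_pairs$gamma)))
  }
  if (!is.null(dose_levels)) stopifnot(all(dose_levels > 0))
  if (!is.null(noise_sd)) stopifnot(all(noise_sd > 0))
  if (!is.null(pathway_blocks)) {
    stopifnot(setequal(unlist(pathway_blocks), seq_len(n_perturbations)))
  }
  structure(as.list(environment()), class = "synth_config")
}

# draw ground-truth generative parameters from the current RNG stream
draw_truth <- function(cfg) {
  p <- cfg$n_genes
  q <- cfg$n_latent_true
  K <- cfg$n_perturbations
  W <- matrix(stats::rnorm(q * p, sd = 1 / sqrt(q)), q, p)
  b <- stats::rnorm(p, cfg$baseline_mean, cfg$baseline_sd)
  noise_sd <- if (is.null(cfg$noise_sd)) stats::runif(p, 0.2, 0.5)
              else rep_len(cfg$noise_sd, p)
  delta <- matrix(0, K, q)
  if (is.null(cfg$pathway_blocks)) {
    delta[] <- stats::rnorm(K * q, sd = cfg$effect_scale)
  } else {
    for (blk in cfg$pathway_blocks) {
      base <- stats::rnorm(q, sd = cfg$effect_scale)
      for (k in blk) {
        delta[k, ] <- base +
          stats::rnorm(q, sd = cfg$block_within_sd * cfg$effect_scale)
      }
    }
  }
  gamma <- matrix(0, K, K)
  if (!is.null(cfg$interaction_pairs)) {
    for (i in seq_len(nrow(cfg$interaction_pairs))) {
      k <- cfg$interaction_pairs$k[i]
      l <- cfg$interaction_pairs$l[i]
      gamma[k, l] <- gamma[l, k] <- cfg$interaction_pairs$gamma[i]
    }
  }
  hill <- NULL
  if (!is.null(cfg$dose_levels)) {
    lr <- log10(range(cfg$dose_levels))
    hill <- data.frame(
      ec50 = 10^stats::runif(K, lr[1L], lr[2L]),
      slope = stats::runif(K, 1, 3))
  }
  list(W = W, b = b, noise_sd = noise_sd, delta = delta, gamma = gamma,
       hill = hill)
}

# latent shift of a condition: combo (indices) at a common dose
condition_shift <- function(truth, combo, dose = 0) {
  if (length(combo) == 0L) return(numeric(ncol(truth$delta)))
  h <- vapply(combo, function(k) {
    if (is.null(truth$hill)) 1
    else hill_response(dose, truth$hill$ec50[k], truth$hill$slope[k])
  }, numeric(1))
  shift <- colSums(truth$delta[combo, , drop = FALSE] * h)
  if (length(combo) >= 2L) {
    for (i in seq_along(combo)) {
      for (j in seq_along(combo)) {
        if (i < j) {
          k <- combo[i]; l <- combo[j]
          shift <- shift + truth$gamma[k, l] * h[i] * h[j] *
            truth$delta[k, ] * truth$delta[l, ]
        }
      }
    }
  }
  shift
}

default_conditions <- function(cfg) {
  singles <- lapply(seq_len(cfg$n_perturbations), identity)
  pairs <- list()
  if (!is.null(cfg$interaction_pairs)) {
    pairs <- lapply(seq_len(nrow(cfg$interaction_pairs)), function(i) {
      sort(c(cfg$interaction_pairs$k[i], cfg$interaction_pairs$l[i]))
    })
  }
  c(singles, pairs)
}

#' Simulate a profile-outcome perturbation screen
#'
#' Generates control cells, perturbed cells for every condition (and dose
#' level, if dosed), a matching treatment design and a random control
#' pairing, together with the generative ground truth used by recovery
#' tests.
#'
#' @param cfg a [synth_config()].
#' @return list with `screen` (a [perturb_screen()]) and `truth`: the
#'   loading matrix `W`, baselines `b`, latent shifts `delta` (K x q),
#'   interaction matrix `gamma`, Hill parameters, noise sds, the per
#'   condition table `conditions` (signature, dose, true mean profile row
#'   index), true mean profiles `condition_means`, `control_mean`, and
#'   `condition_of` mapping each outcome row to its condition.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- cfg$n_genes
  q <- cfg$n_latent_true
  K <- cfg$n_perturbations
  pert_ids <- sprintf("P%d", seq_len(K))
  gene_ids <- sprintf("G%04d", seq_len(p))

  withr::with_seed(cfg$seed, {
    truth <- draw_truth(cfg)
    combos <- if (is.null(cfg$conditions)) default_conditions(cfg)
              else cfg$conditions
    doses <- if (is.null(cfg$dose_levels)) 0 else cfg$dose_levels
    cond <- expand.grid(ci = seq_along(combos), di = seq_along(doses))
    n_cond <- nrow(cond)

    sim_cells <- function(n, shift) {
      L <- matrix(stats::rnorm(n * q, sd = cfg$cell_latent_sd), n, q)
      U <- sweep(L, 2L, -shift, "-") %*% truth$W
      U <- sweep(U, 2L, truth$b, "+")
      softplus(U) +
        matrix(stats::rnorm(n * p), n, p) %*% diag(truth$noise_sd, p)
    }

    controls <- sim_cells(cfg$n_controls, numeric(q))
    rownames(controls) <- sprintf("ctrl%05d", seq_len(cfg$n_controls))
    colnames(controls) <- gene_ids

    nc <- cfg$n_cells_per_condition
    Ymat <- matrix(0, n_cond * nc, p)
    Tm <- matrix(0, n_cond * nc, K)
    Dm <- if (!is.null(cfg$dose_levels)) matrix(0, n_cond * nc, K)
    condition_of <- integer(n_cond * nc)
    cond_means <- matrix(0, n_cond, p)
    sig <- character(n_cond)
    dose_of <- numeric(n_cond)
    for (ci in seq_len(n_cond)) {
      combo <- combos[[cond$ci[ci]]]
      dose <- doses[cond$di[ci]]
      shift <- condition_shift(truth, combo, dose)
      rows <- (ci - 1L) * nc + seq_len(nc)
      Ymat[rows, ] <- sim_cells(nc, shift)
      Tm[rows, combo] <- 1
      if (!is.null(Dm)) Dm[rows, combo] <- dose
      condition_of[rows] <- ci
      cond_means[ci, ] <- softplus(truth$b + drop(shift %*% truth$W))
      sig[ci] <- paste(sort(pert_ids[combo]), collapse = "+")
      dose_of[ci] <- dose
    }
    rownames(Ymat) <- sprintf("cell%06d", seq_len(nrow(Ymat)))
    colnames(Ymat) <- gene_ids
    pairing <- sample.int(cfg$n_controls, nrow(Ymat), replace = TRUE)
  })

  colnames(cond_means) <- gene_ids
  screen <- perturb_screen(
    controls = expression_matrix(controls),
    design = treatment_design(Tm, pert_ids, dosages = Dm),
    outcomes = expression_matrix(Ymat),
    pairing = pairing)
  truth$conditions <- data.frame(signature = sig, dose = dose_of,
                                 combo = I(lapply(seq_len(n_cond), function(ci)
                                   combos[[cond$ci[ci]]])))
  truth$condition_means <- cond_means
  truth$control_mean <- softplus(truth$b)
  truth$condition_of <- condition_of
  truth$perturbation_ids <- pert_ids
  truth$pathway_blocks <- cfg$pathway_blocks
  list(screen = screen, truth = truth)
}

#' Simulate a scalar-outcome (drug-synergy) screen
#'
#' Bulk cell-line profiles are drawn from the latent-factor model; the
#' outcome of pair (k, l) on cell line c is
#' `y = v . L_c + s_k + s_l + gamma_kl + noise`, where `v . L_c` is a
#' cell-line (context) effect, `s_k` are single-drug main effects and
#' `gamma_kl` is the ground-truth synergy the model must recover.
#'
#' @param cfg a [synth_config()]; `interaction_pairs` defines the measured
#'   pairs and their synergies (default: all pairs, `gamma = 0`),
#'   `n_cell_lines` the number of profiles, `n_replicates` replicate
#'   measurements per (line, pair), `synergy_noise_sd` the outcome noise.
#' @return list with `screen` (scalar outcomes) and `truth` (`s`, `gamma`,
#'   `v`, cell-line latents `L`, analytic mean per triplet).
#' @export
simulate_synergy_screen <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- cfg$n_genes
  q <- cfg$n_latent_true
  K <- cfg$n_perturbations
  pert_ids <- sprintf("P%d", seq_len(K))
  gene_ids <- sprintf("G%04d", seq_len(p))

  pairs <- if (is.null(cfg$interaction_pairs)) {
    all_p <- utils::combn(K, 2L)
    data.frame(k = all_p[1L, ], l = all_p[2L, ], gamma = 0)
  } else cfg$interaction_pairs

  withr::with_seed(cfg$seed, {
    truth <- draw_truth(cfg)
    nl <- cfg$n_cell_lines
    L <- matrix(stats::rnorm(nl * q), nl, q)
    X <- softplus(sweep(L %*% truth$W, 2L, truth$b, "+")) +
      matrix(stats::rnorm(nl * p), nl, p) %*% diag(truth$noise_sd, p)
    rownames(X) <- sprintf("line%03d", seq_len(nl))
    colnames(X) <- gene_ids
    s <- stats::rnorm(K, 0, 2)
    v <- stats::rnorm(q)

    grid <- expand.grid(line = seq_len(nl), pair = seq_len(nrow(pairs)),
                        rep = seq_len(max(1L, cfg$n_replicates)))
    mu <- drop(L[grid$line, , drop = FALSE] %*% v) +
      s[pairs$k[grid$pair]] + s[pairs$l[grid$pair]] +
      pairs$gamma[grid$pair]
    y <- mu + stats::rnorm(nrow(grid), 0, cfg$synergy_noise_sd)
    Tm <- matrix(0, nrow(grid), K)
    Tm[cbind(seq_len(nrow(grid)), pairs$k[grid$pair])] <- 1
    Tm[cbind(seq_len(nrow(grid)), pairs$l[grid$pair])] <- 1
  })

  screen <- perturb_screen(
    controls = expression_matrix(X),
    design = treatment_design(Tm, pert_ids),
    outcomes = y,
    pairing = grid$line)
  truth$s <- s
  truth$v <- v
  truth$L <- L
  truth$pairs <- pairs
  truth$mean_outcome <- mu
  truth$triplets <- grid
  truth$perturbation_ids <- pert_ids
  list(screen = screen, truth = truth)
}

#' Derive a gene-set annotation from simulation truth
#'
#' Builds a GMT-compatible annotation in which perturbation targets of the
#' same pathway block share block pathways (plus a few private ones per
#' gene), so truly similar perturbations receive high Jaccard similarity
#' and cross-block pairs similarity zero.
#'
#' @param truth the `truth` component of [simulate_screen()] (needs
#'   `pathway_blocks`).
#' @param n_shared shared pathways per block.
#' @param n_private private pathways per gene.
#' @return A [gene_set_annotation()] over the perturbation ids.
#' @export
gmt_from_truth <- function(truth, n_shared = 3L, n_private = 2L) {
  blocks <- truth$pathway_blocks
  if (is.null(blocks)) {
    stop("truth carries no pathway blocks", call. = FALSE)
  }
  ids <- truth$perturbation_ids
  membership <- stats::setNames(vector("list", length(ids)), ids)
  for (bi in seq_along(blocks)) {
    shared <- sprintf("BLK%d_S%d", bi, seq_len(n_shared))
    for (k in blocks[[bi]]) {
      membership[[ids[k]]] <- c(shared,
                                sprintf("PRIV_%s_%d", ids[k],
                                        seq_len(n_private)))
    }
  }
  gene_set_annotation(membership)
}
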