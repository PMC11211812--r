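# Shared fixtures, built in code.

toy_expr <- function(n = 5L, p = 8L, seed = 42L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p, mean = 2), n, p)
    expression_matrix(m, sprintf("g%02d", seq_len(p)),
                      sprintf("s%02d", seq_len(n)))
  })
}

# a tiny profile-outcome screen with hand-set design
toy_screen <- function(seed = 7L) {
  withr::with_seed(seed, {
    controls <- expression_matrix(matrix(rnorm(4 * 6, 2), 4, 6),
                                  sprintf("g%d", 1:6), sprintf("c%d", 1:4))
    Tm <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))
    design <- treatment_design(Tm, c("A", "B", "C"))
    outcomes <- expression_matrix(matrix(rnorm(4 * 6, 3), 4, 6,
                                         dimnames = list(sprintf("y%d", 1:4),
                                                         sprintf("g%d", 1:6))))
    perturb_screen(controls, design, outcomes, pairing = c(1L, 2L, 3L, 4L))
  })
}

small_model <- function(head = "gaussian", p = 6L, K = 3L, latent = 4L,
                        seed = 11L, dose_transform = "none",
                        dose_levels = NULL) {
  cfg <- codex_config(latent_dim = latent, encoder_widths = 5L,
                      branch_widths = integer(0), decoder_widths = 5L,
                      head = head, dose_transform = dose_transform,
                      seed = seed)
  codex_model(cfg, p, sprintf("P%d", seq_len(K)), n_outcome = p,
              dose_levels = dose_levels)
}

# naive forward: evaluates EVERY branch and weights it, including zeros
naive_forward <- function(model, x, t, dose = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  H <- encode(model, X)
  K <- length(model$perturbation_ids)
  Z <- matrix(0, nrow(X), model$config$latent_dim)
  for (k in seq_len(K)) {
    dk <- if (!is.null(dose)) {
      D <- if (is.matrix(dose)) dose else matrix(dose, nrow = 1L)
      D[rep_len(seq_len(nrow(D)), nrow(X)), k]
    }
    B <- branch_apply(model, H, k, dk)
    Tm <- if (is.matrix(t)) t else matrix(t, nrow = 1L)
    Z <- Z + Tm[rep_len(seq_len(nrow(Tm)), nrow(X)), k] * B
  }
  if (model$config$head == "scalar") decode_scalar(model, Z)
  else decode_gaussian(model, Z)
}
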