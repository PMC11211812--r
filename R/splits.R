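# Cross-validation split generators and their post-hoc validators.

#' Generate cross-validation splits
#'
#' Three schemes: `random_triplet` partitions experiments at random (test
#' combinations may also occur in training, only the triplets differ);
#' `leave_combination_out` partitions the distinct treatment combinations,
#' so no test-fold combination (as a set of perturbation ids) occurs in
#' its training fold; `leave_perturbation_out` holds out whole
#' perturbations per fold, with `seen_mode` selecting which experiments
#' form the test set: `"0of1"` singles of a held-out perturbation,
#' `"1of2"` pairs with exactly one held-out member, `"0of2"` pairs with
#' both members held out. In all `leave_perturbation_out` modes the
#' training fold contains no experiment involving a held-out perturbation.
#'
#' @param screen a [perturb_screen()].
#' @param scheme one of `"random_triplet"`, `"leave_combination_out"`,
#'   `"leave_perturbation_out"`.
#' @param n_folds number of folds.
#' @param seed integer seed; splits are reproducible.
#' @param seen_mode for `leave_perturbation_out`: `"0of1"`, `"1of2"` or
#'   `"0of2"`.
#' @param perts_per_fold perturbations held out per fold
#'   (`leave_perturbation_out`; default 1, use 2+ for `"0of2"`).
#' @return A `split_spec`: list with `folds` (each `list(train, test)`),
#'   `scheme`, `seen_mode`.
#' @export
make_splits <- function(screen,
                        scheme = c("random_triplet", "leave_combination_out",
                                   "leave_perturbation_out"),
                        n_folds = 5L, seed = 1L, seen_mode = NULL,
                        perts_per_fold = 1L) {
  scheme <- match.arg(scheme)
  n <- n_triplets(screen)
  sig <- combo_signature(screen$design)
  folds <- withr::with_seed(seed, {
    if (scheme == "random_triplet") {
      grp <- sample(rep_len(seq_len(n_folds), n))
      lapply(seq_len(n_folds), function(f) {
        list(train = which(grp != f), test = which(grp == f))
      })
    } else if (scheme == "leave_combination_out") {
      combos <- unique(sig)
      if (length(combos) < n_folds) {
        stop("fewer distinct combinations than folds", call. = FALSE)
      }
      grp <- sample(rep_len(seq_len(n_folds), length(combos)))
      lapply(seq_len(n_folds), function(f) {
        test_combos <- combos[grp == f]
        list(train = which(!sig %in% test_combos),
             test = which(sig %in% test_combos))
      })
    } else {
      if (is.null(seen_mode)) {
        stop("seen_mode required for leave_perturbation_out", call. = FALSE)
      }
      seen_mode <- match.arg(seen_mode, c("0of1", "1of2", "0of2"))
      perts <- screen$design$perturbation_ids
      if (length(perts) < n_folds * perts_per_fold) {
        stop("not enough perturbations for the requested folds", call. = FALSE)
      }
      held <- split(sample(perts, n_folds * perts_per_fold),
                    rep(seq_len(n_folds), each = perts_per_fold))
      active <- screen$design$matrix != 0
      lapply(seq_len(n_folds), function(f) {
        h <- held[[f]]
        hcols <- match(h, perts)
        n_held <- rowSums(active[, hcols, drop = FALSE])
        n_active <- rowSums(active)
        test <- switch(seen_mode,
          "0of1" = which(n_active == 1L & n_held == 1L),
          "1of2" = which(n_active == 2L & n_held == 1L),
          "0of2" = which(n_active == 2L & n_held == 2L))
        list(train = which(n_held == 0L), test = test,
             held_out = h)
      })
    }
  })
  structure(list(folds = folds, scheme = scheme,
                 seen_mode = if (scheme == "leave_perturbation_out")
                   seen_mode else NULL),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %s%s, %d folds\n", x$scheme,
              if (!is.null(x$seen_mode)) paste0(" (", x$seen_mode, ")") else "",
              length(x$folds)))
  invisible(x)
}

#' Validate split guarantees post hoc
#'
#' Re-checks the scheme's disjointness guarantees against the screen:
#' train/test indices disjoint in every fold; under
#' `leave_combination_out`, no test combination occurs in its training
#' fold; under `leave_perturbation_out`, no held-out perturbation occurs
#' in any training-fold design row.
#'
#' @param screen the [perturb_screen()] the splits were generated from.
#' @param split a `split_spec` from [make_splits()].
#' @return `TRUE` invisibly; errors on any violated guarantee.
#' @export
validate_splits <- function(screen, split) {
  sig <- combo_signature(screen$design)
  for (f in seq_along(split$folds)) {
    fold <- split$folds[[f]]
    if (length(intersect(fold$train, fold$test)) > 0L) {
      stop("fold ", f, ": train and test indices overlap", call. = FALSE)
    }
    if (split$scheme == "leave_combination_out") {
      leaked <- intersect(unique(sig[fold$test]), unique(sig[fold$train]))
      if (length(leaked) > 0L) {
        stop("fold ", f, ": combinations leaked into training: ",
             paste(leaked, collapse = ", "), call. = FALSE)
      }
    }
    if (split$scheme == "leave_perturbation_out") {
      hcols <- match(fold$held_out, screen$design$perturbation_ids)
      leak <- screen$design$matrix[fold$train, hcols, drop = FALSE]
      if (any(leak != 0)) {
        stop("fold ", f, ": held-out perturbation appears in training rows",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
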