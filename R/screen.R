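#' Construct a treatment design
#'
#' Encodes which interventions were applied in each experiment as a
#' samples x K multi-hot matrix, with optional per-intervention dosages.
#' Observed designs are strictly 0/1; fractional weights only arise later,
#' in proxy-augmented effective treatment rows built by
#' [effective_treatment()].
#'
#' @param matrix samples x K numeric matrix with entries in \{0, 1\}.
#' @param perturbation_ids names of the K interventions (column order).
#' @param dosages optional samples x K matrix of raw doses on a declared
#'   scale; 0 is the sentinel for "no dose recorded", so undosed screens
#'   degrade to the pure multi-hot case.
#' @return A `treatment_design` object.
#' @export
treatment_design <- function(matrix, perturbation_ids = colnames(matrix),
                             dosages = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (is.null(perturbation_ids)) {
    stop("perturbation_ids are required", call. = FALSE)
  }
  perturbation_ids <- as.character(perturbation_ids)
  if (length(perturbation_ids) != ncol(m)) {
    stop("perturbation_ids length does not match design columns", call. = FALSE)
  }
  if (anyDuplicated(perturbation_ids)) {
    stop("perturbation_ids must be unique", call. = FALSE)
  }
  if (anyNA(m)) stop("design contains missing entries", call. = FALSE)
  if (!all(m %in% c(0, 1))) {
    stop("observed design entries must be 0 or 1", call. = FALSE)
  }
  colnames(m) <- perturbation_ids
  if (!is.null(dosages)) {
    dosages <- as.matrix(dosages)
    storage.mode(dosages) <- "double"
    if (!all(dim(dosages) == dim(m))) {
      stop("dosages must match the design dimensions", call. = FALSE)
    }
    if (anyNA(dosages) || any(dosages < 0)) {
      stop("dosages must be nonnegative (0 = no dose recorded)", call. = FALSE)
    }
    colnames(dosages) <- perturbation_ids
  }
  structure(list(matrix = m, perturbation_ids = perturbation_ids,
                 dosages = dosages),
            class = "treatment_design")
}

#' @export
print.treatment_design <- function(x, ...) {
  cat(sprintf("<treatment_design> %d samples x %d interventions%s\n",
              nrow(x$matrix), length(x$perturbation_ids),
              if (is.null(x$dosages)) "" else " (dosed)"))
  invisible(x)
}

#' Assemble a perturbation screen
#'
#' Bundles the training triplets: a control (unperturbed) expression
#' matrix, a treatment design, the recorded outcomes, and the pairing that
#' assigns every outcome row its control profile. Outcomes are either a
#' named numeric vector of scalar responses (e.g. precomputed ZIP synergy
#' scores) or an [expression_matrix()] of perturbed profiles; the kind is
#' uniform within a screen.
#'
#' @param controls [expression_matrix()] of unperturbed profiles.
#' @param design [treatment_design()] with one row per outcome.
#' @param outcomes numeric vector (scalar screen) or [expression_matrix()]
#'   (profile screen), rows aligned with the design.
#' @param pairing integer vector: for each outcome row, the row index of
#'   its control profile in `controls`.
#' @return A `perturb_screen` object.
#' @export
perturb_screen <- function(controls, design, outcomes, pairing) {
  stopifnot(inherits(controls, "expression_matrix"),
            inherits(design, "treatment_design"))
  n <- nrow(design$matrix)
  if (inherits(outcomes, "expression_matrix")) {
    kind <- "profile"
    if (nrow(outcomes) != n) {
      stop("outcome rows do not match design rows", call. = FALSE)
    }
    if (!identical(colnames(outcomes), colnames(controls))) {
      stop("outcome and control gene identifiers differ", call. = FALSE)
    }
  } else {
    kind <- "scalar"
    outcomes <- as.numeric(outcomes)
    if (length(outcomes) != n) {
      stop("outcome length does not match design rows", call. = FALSE)
    }
    if (anyNA(outcomes)) stop("scalar outcomes contain NA", call. = FALSE)
  }
  pairing <- as.integer(pairing)
  if (length(pairing) != n || anyNA(pairing) ||
      any(pairing < 1L) || any(pairing > nrow(controls))) {
    stop("pairing must map every outcome row to a control row", call. = FALSE)
  }
  structure(list(controls = controls, design = design, outcomes = outcomes,
                 pairing = pairing, outcome_kind = kind),
            class = "perturb_screen")
}

#' @export
print.perturb_screen <- function(x, ...) {
  cat(sprintf(
    "<perturb_screen> %d triplets, %d controls, %d genes, %d interventions, %s outcomes\n",
    nrow(x$design$matrix), nrow(x$controls), ncol(x$controls),
    length(x$design$perturbation_ids), x$outcome_kind))
  invisible(x)
}

n_triplets <- function(screen) nrow(screen$design$matrix)

#' Pair perturbed cells with control cells
#'
#' Single-cell perturbation assays are destructive: the same cell is never
#' observed before and after the intervention, so a pseudo-pairing must be
#' chosen. `random_control` draws one control cell uniformly per perturbed
#' cell (reproducible under `seed`); `mean_control` pairs every cell with
#' the control centroid (a synthetic mean profile appended to the
#' controls).
#'
#' @param perturbed [expression_matrix()] of perturbed cells.
#' @param controls [expression_matrix()] of control cells.
#' @param strategy `"random_control"` (default) or `"mean_control"`.
#' @param seed integer seed for the random strategy.
#' @return list with `controls` (possibly augmented) and integer `pairing`.
#' @export
pair_controls <- function(perturbed, controls,
                          strategy = c("random_control", "mean_control"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  if (nrow(controls) == 0L) stop("empty control set", call. = FALSE)
  n <- nrow(perturbed)
  if (strategy == "random_control") {
    pairing <- withr::with_seed(seed,
      sample.int(nrow(controls), n, replace = TRUE))
    list(controls = controls, pairing = pairing)
  } else {
    centroid <- matrix(colMeans(unclass(controls)), 1L,
                       dimnames = list("control_centroid", colnames(controls)))
    aug <- expression_matrix(rbind(unclass(controls), centroid))
    list(controls = aug, pairing = rep(nrow(aug), n))
  }
}
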