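#' Gene-set annotation
#'
#' Maps each gene to the set of pathways containing it; the basis of the
#' proxy scheme for unobserved perturbations. Empty sets are allowed.
#'
#' @param membership named list: gene id -> character vector of pathway
#'   ids.
#' @return A `gene_set_annotation` object.
#' @export
gene_set_annotation <- function(membership) {
  if (is.null(names(membership)) || anyDuplicated(names(membership))) {
    stop("membership must be a uniquely named list (gene -> pathways)",
         call. = FALSE)
  }
  membership <- lapply(membership, function(p) unique(as.character(p)))
  structure(list(membership = membership), class = "gene_set_annotation")
}

#' @export
print.gene_set_annotation <- function(x, ...) {
  cat(sprintf("<gene_set_annotation> %d genes, %d pathways\n",
              length(x$membership),
              length(unique(unlist(x$membership)))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' `read_gmt` parses a GMT file (one pathway per line: id, description,
#' member genes) into a [gene_set_annotation()]; genes listed in
#' `universe` but in no pathway get empty sets. `write_gmt` emits the
#' inverse representation (pathway -> genes) as GMT.
#'
#' @param path GMT file path.
#' @param universe optional character vector of gene ids that must all be
#'   present in the returned annotation.
#' @param ann a [gene_set_annotation()].
#' @return `read_gmt`: a [gene_set_annotation()]; `write_gmt`: the path,
#'   invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  pathways <- fgsea::gmtPathways(path)
  genes <- unique(c(unlist(pathways, use.names = FALSE), universe))
  membership <- stats::setNames(
    lapply(genes, function(g) character(0)), genes)
  for (pw in names(pathways)) {
    for (g in pathways[[pw]]) {
      membership[[g]] <- c(membership[[g]], pw)
    }
  }
  gene_set_annotation(membership)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "gene_set_annotation"))
  pw <- list()
  for (g in names(ann$membership)) {
    for (p in ann$membership[[g]]) pw[[p]] <- c(pw[[p]], g)
  }
  lines <- vapply(names(pw), function(p) {
    paste(c(p, "na", pw[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Jaccard pathway similarity between two genes
#'
#' The fraction of shared pathways, `|N_j intersect N_j'| / |N_j union
#' N_j'|`, where `N_u` is the set of pathways containing gene `u`; defined
#' as 0 when both sets are empty.
#'
#' @param j,jp gene ids present in `ann`.
#' @param ann a [gene_set_annotation()].
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(j, jp, ann) {
  m <- ann$membership
  for (g in c(j, jp)) {
    if (!g %in% names(m)) stop("unknown gene: ", g, call. = FALSE)
  }
  a <- m[[j]]
  b <- m[[jp]]
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix
#'
#' @param genes character vector of gene ids.
#' @param ann a [gene_set_annotation()].
#' @return symmetric matrix of pairwise similarities (unit diagonal for
#'   genes with nonempty sets).
#' @export
similarity_matrix <- function(genes, ann) {
  n <- length(genes)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (k in i:n) {
      S[i, k] <- S[k, i] <- jaccard_similarity(genes[i], genes[k], ann)
    }
  }
  S
}

#' Build a proxy treatment vector for an unobserved perturbation
#'
#' Weights each observed perturbation by its Jaccard similarity to the
#' unseen target and L1-normalizes, so the weights sum to 1 whenever any
#' similarity is nonzero. A target similar to none of the observed
#' perturbations yields the all-zero proxy (decoding it gives the model's
#' control-state prediction) with `degenerate = TRUE`.
#'
#' @param target unseen perturbation (gene) id.
#' @param observed character vector of observed perturbation ids (single
#'   perturbations only; combinations are never proxy anchors).
#' @param ann a [gene_set_annotation()].
#' @return A `proxy_vector`: list with `weights` (named length-K vector),
#'   `target` and `degenerate`.
#' @export
build_proxy <- function(target, observed, ann) {
  if (target %in% observed) {
    stop("target is among the observed perturbations; no proxy needed",
         call. = FALSE)
  }
  sims <- vapply(observed, function(g) jaccard_similarity(target, g, ann),
                 numeric(1))
  total <- sum(sims)
  degenerate <- total == 0
  w <- if (degenerate) sims else sims / total
  if (degenerate) {
    warning("target '", target,
            "' shares no pathways with any observed perturbation; ",
            "returning the all-zero proxy", call. = FALSE)
  }
  structure(list(weights = w, target = target, degenerate = degenerate),
            class = "proxy_vector")
}

#' @export
print.proxy_vector <- function(x, ...) {
  cat(sprintf("<proxy_vector> target %s over %d observed perturbations%s\n",
              x$target, length(x$weights),
              if (x$degenerate) " (degenerate: all-zero)" else ""))
  invisible(x)
}

#' Combine observed treatments with proxy vectors
#'
#' The effective treatment row is the elementwise sum of the observed
#' multi-hot row and every proxy's weight vector; e.g. observed
#' `(1,0,0,0,0)` plus proxy `(0,0.4,0.35,0.25,0)` gives
#' `(1,0.4,0.35,0.25,0)`. Proxies are not re-normalized on combination,
#' so each contributes total mass 1.
#'
#' @param observed_row numeric length-K multi-hot vector (may be all
#'   zero when every perturbation in the experiment is unseen).
#' @param proxies a single [build_proxy()] result or a list of them; their
#'   weight vectors must have length K.
#' @return numeric length-K effective treatment row.
#' @export
effective_treatment <- function(observed_row, proxies = list()) {
  if (inherits(proxies, "proxy_vector")) proxies <- list(proxies)
  t_eff <- as.numeric(observed_row)
  for (pv in proxies) {
    w <- if (inherits(pv, "proxy_vector")) pv$weights else as.numeric(pv)
    if (length(w) != length(t_eff)) {
      stop("proxy weight length does not match the treatment row",
           call. = FALSE)
    }
    t_eff <- t_eff + w
  }
  names(t_eff) <- names(observed_row)
  t_eff
}
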