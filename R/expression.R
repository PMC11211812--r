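#' Construct an expression matrix
#'
#' A light container for log-scale expression values: a samples x genes
#' numeric matrix with unique gene and sample identifiers. All modelling
#' functions in the package assume inputs are already normalized and
#' log-transformed; no count handling is performed here.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param sample_ids character vector of sample/cell identifiers (rows).
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   `dimnames = list(sample_ids, gene_ids)`.
#' @examples
#' em <- expression_matrix(matrix(1:6, 2, 3), paste0("g", 1:3), c("s1", "s2"))
#' dim(em)
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("gene_ids length does not match column count", call. = FALSE)
  }
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length does not match row count", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyNA(values)) stop("expression values contain missing entries", call. = FALSE)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes\n", nrow(x), ncol(x)))
  invisible(x)
}

gene_ids <- function(x) colnames(x)
sample_ids_of <- function(x) rownames(x)

# Subset while keeping the class; `[` on the underlying matrix would drop it.
em_subset <- function(x, i = NULL, j = NULL) {
  v <- unclass(x)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v)
}

#' Filter lowly expressed, low-variance genes
#'
#' A gene is dropped when it is lowly expressed (maximum log-expression
#' below `min_expr`) *and* its variance across samples is below `min_var`.
#' A gene passing either rule is retained, so informative but lowly
#' expressed genes survive, as do flat but well-expressed ones. Gene order
#' is preserved.
#'
#' @param expr an [expression_matrix()] on log scale.
#' @param min_expr expression threshold (log units; default 1, i.e. genes
#'   never reaching log2(RPKM+1) of 1 are candidates for removal).
#' @param min_var variance threshold (default 0.8).
#' @return The filtered [expression_matrix()].
#' @examples
#' em <- expression_matrix(cbind(a = c(0.5, 0.5), b = c(0, 2)),
#'                         sample_ids = c("s1", "s2"))
#' colnames(filter_genes(em))  # "a" is flat and low: dropped
#' @export
filter_genes <- function(expr, min_expr = 1, min_var = 0.8) {
  v <- unclass(expr)
  max_e <- apply(v, 2L, max)
  vars <- apply(v, 2L, stats::var)
  if (nrow(v) < 2L) vars[] <- 0
  drop <- (max_e < min_expr) & (vars < min_var)
  if (all(drop)) stop("all genes removed by filter_genes", call. = FALSE)
  em_subset(expr, j = which(!drop))
}

#' Select the most variable genes
#'
#' Keeps the `n` genes of largest variance across samples; ties at the
#' cutoff are broken in favour of the earlier-indexed gene. Relative gene
#' order of the selected genes is preserved.
#'
#' @param expr an [expression_matrix()].
#' @param n number of genes to keep.
#' @return The reduced [expression_matrix()].
#' @export
select_hvg <- function(expr, n) {
  if (length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (n > ncol(expr)) stop("n exceeds the number of genes", call. = FALSE)
  vars <- apply(unclass(expr), 2L, stats::var)
  keep <- sort(order(-vars, seq_along(vars))[seq_len(n)])
  em_subset(expr, j = keep)
}
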