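# Readers and writers for screens. Supported on-disk formats:
#   csv / tsv : expression as a table with sample (or gene) ids in the first
#               column; orientation is auto-detected by matching identifiers
#               against the design table.
#   mtx       : MatrixMarket genes x samples matrix with sidecar id lists
#               <prefix>.genes.txt and <prefix>.samples.txt (one id per line).
# The design table is always delimited text with columns:
#   sample_id, control_id, one 0/1 column per perturbation, and optional
#   dose_<perturbation> columns holding raw doses (0 = none recorded).
# Identifier matching is case-sensitive and exact.

read_delim_table <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

read_expr_table <- function(path, sep) {
  tab <- read_delim_table(path, sep)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

read_expr_mtx <- function(path) {
  prefix <- sub("\\.mtx$", "", path)
  genes_f <- paste0(prefix, ".genes.txt")
  samples_f <- paste0(prefix, ".samples.txt")
  if (!file.exists(genes_f) || !file.exists(samples_f)) {
    stop("sidecar id files not found next to ", path, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(genes_f)
  samples <- readLines(samples_f)
  if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
    stop("MTX dimensions do not match sidecar id lists", call. = FALSE)
  }
  dimnames(m) <- list(genes, samples)
  t(m)  # stored genes x samples; return samples x genes
}

# orient a raw matrix so that rows are `wanted` sample ids
orient_expr <- function(m, wanted, what) {
  if (all(wanted %in% rownames(m))) return(m)
  if (all(wanted %in% colnames(m))) return(t(m))
  missing <- setdiff(wanted, union(rownames(m), colnames(m)))
  stop(sprintf("%s: identifiers not found in expression data: %s", what,
               paste(utils::head(missing, 5L), collapse = ", ")),
       call. = FALSE)
}

parse_design_table <- function(tab) {
  need <- c("sample_id", "control_id")
  if (!all(need %in% names(tab))) {
    stop("design table needs sample_id and control_id columns", call. = FALSE)
  }
  other <- setdiff(names(tab), need)
  dose_cols <- grep("^dose_", other, value = TRUE)
  pert_cols <- setdiff(other, dose_cols)
  if (length(pert_cols) == 0L) stop("design table has no perturbation columns",
                                    call. = FALSE)
  m <- as.matrix(tab[, pert_cols, drop = FALSE])
  dosages <- NULL
  if (length(dose_cols)) {
    dosages <- matrix(0, nrow(m), length(pert_cols),
                      dimnames = list(NULL, pert_cols))
    for (dc in dose_cols) {
      p <- sub("^dose_", "", dc)
      if (!p %in% pert_cols) {
        stop("dose column refers to unknown perturbation: ", p, call. = FALSE)
      }
      dosages[, p] <- tab[[dc]]
    }
  }
  list(design = treatment_design(m, pert_cols, dosages),
       sample_id = as.character(tab$sample_id),
       control_id = as.character(tab$control_id))
}

#' Load a perturbation screen from disk
#'
#' Reads the control expression matrix, the treatment design table and the
#' outcomes, aligns everything by identifier (never by position), and
#' returns a validated [perturb_screen()]. The outcome file either holds a
#' scalar response per experiment (columns `sample_id`, `score`) or a
#' perturbed expression matrix in the same format as the controls.
#'
#' @param expr_path control expression file (`.csv`/`.tsv` table or `.mtx`).
#' @param design_path design table (delimited text, see Details).
#' @param outcome_path outcome file (scalar table, or expression matrix).
#' @param format `"csv"`, `"tsv"` or `"mtx"` (expression files; the design
#'   is delimited text in all cases).
#' @return A [perturb_screen()].
#' @details The design table columns are `sample_id` (outcome identifier),
#'   `control_id` (which control profile the experiment started from), one
#'   0/1 column per perturbation, and optional `dose_<perturbation>`
#'   columns with raw dosages (0 meaning no dose recorded).
#' @export
load_screen <- function(expr_path, design_path, outcome_path,
                        format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  dsep <- if (grepl("\\.tsv$", design_path)) "\t" else sep
  des <- parse_design_table(read_delim_table(design_path, dsep))

  raw_expr <- if (format == "mtx") read_expr_mtx(expr_path)
              else read_expr_table(expr_path, sep)
  if (anyNA(raw_expr)) stop("control expression contains NA", call. = FALSE)
  expr <- orient_expr(raw_expr, unique(des$control_id), "design control_id")
  controls <- expression_matrix(expr)

  # outcome: peek at the header to decide scalar vs profile
  scalar <- FALSE
  osep <- if (grepl("\\.tsv$", outcome_path)) "\t" else ","
  if (!grepl("\\.mtx$", outcome_path)) {
    hdr <- names(read_delim_table(outcome_path, osep)[0, ])
    scalar <- identical(sort(hdr), sort(c("sample_id", "score")))
  }
  if (scalar) {
    otab <- read_delim_table(outcome_path, osep)
    idx <- match(des$sample_id, as.character(otab$sample_id))
    if (anyNA(idx)) {
      stop("outcomes missing for samples: ",
           paste(utils::head(des$sample_id[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    outcomes <- as.numeric(otab$score[idx])
  } else {
    raw_out <- if (grepl("\\.mtx$", outcome_path)) read_expr_mtx(outcome_path)
               else read_expr_table(outcome_path, osep)
    if (anyNA(raw_out)) stop("outcome expression contains NA", call. = FALSE)
    raw_out <- orient_expr(raw_out, des$sample_id, "design sample_id")
    raw_out <- raw_out[des$sample_id, colnames(controls), drop = FALSE]
    outcomes <- expression_matrix(raw_out)
  }

  pairing <- match(des$control_id, rownames(controls))
  if (anyNA(pairing)) {
    stop("design references controls absent from expression data: ",
         paste(utils::head(des$control_id[is.na(pairing)], 5L), collapse = ", "),
         call. = FALSE)
  }
  perturb_screen(controls, des$design, outcomes, pairing)
}

#' Write a perturbation screen to disk
#'
#' Writes `controls`, `design` and `outcomes` files into `dir` in a layout
#' [load_screen()] reads back; values round-trip at full stored precision
#' (text formats use 17 significant digits).
#'
#' @param screen a [perturb_screen()].
#' @param dir output directory (created if missing).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return Invisibly, a named list of the written paths.
#' @export
write_screen <- function(screen, dir, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  ext <- if (format == "tsv") "tsv" else "csv"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  write_expr <- function(em, stem) {
    if (format == "mtx") {
      path <- file.path(dir, paste0(stem, ".mtx"))
      Matrix::writeMM(Matrix::Matrix(t(unclass(em)), sparse = TRUE), path)
      writeLines(colnames(em), file.path(dir, paste0(stem, ".genes.txt")))
      writeLines(rownames(em), file.path(dir, paste0(stem, ".samples.txt")))
      path
    } else {
      path <- file.path(dir, paste0(stem, ".", ext))
      df <- data.frame(sample_id = rownames(em),
                       format(unclass(em), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       check.names = FALSE)
      utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
      path
    }
  }

  expr_path <- write_expr(screen$controls, "controls")
  d <- screen$design
  dtab <- data.frame(sample_id = outcome_ids(screen),
                     control_id = rownames(screen$controls)[screen$pairing],
                     d$matrix, check.names = FALSE)
  if (!is.null(d$dosages)) {
    dd <- d$dosages
    colnames(dd) <- paste0("dose_", d$perturbation_ids)
    dtab <- cbind(dtab, dd)
  }
  design_path <- file.path(dir, paste0("design.", ext))
  utils::write.table(dtab, design_path, sep = sep, row.names = FALSE,
                     quote = FALSE)

  if (screen$outcome_kind == "scalar") {
    outcome_path <- file.path(dir, paste0("outcomes.", ext))
    utils::write.table(
      data.frame(sample_id = outcome_ids(screen),
                 score = format(screen$outcomes, digits = 17, trim = TRUE)),
      outcome_path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    outcome_path <- write_expr(screen$outcomes, "outcomes")
  }
  invisible(list(expr = expr_path, design = design_path,
                 outcome = outcome_path))
}

# identifiers of the outcome rows (profile rownames, or synthesized)
outcome_ids <- function(screen) {
  if (screen$outcome_kind == "profile") rownames(screen$outcomes)
  else sprintf("exp%05d", seq_len(n_triplets(screen)))
}
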