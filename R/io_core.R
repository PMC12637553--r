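#' @useDynLib spanmf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Functional categories recognised on gene panels. Panels may leave the
# category column empty; anything outside this vocabulary is rejected.
PANEL_CATEGORIES <- c(
  "gene expression regulation", "axons", "neuronal communication",
  "WNT signalling", "cell cycle", "dendrites"
)

#' Construct a validated spatial expression matrix
#'
#' Bundles a sparse raw count matrix with aligned cell and gene metadata.
#' Counts are stored sparse (`Matrix::dgCMatrix`); rows are cells, columns
#' are genes, and dimnames carry the identifiers.
#'
#' @param counts non-negative integer matrix (cells x genes), dense or sparse.
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um`,
#'   `batch_id`, `individual_id`, `sex`, `region_label` and optionally
#'   `system_label`. One row per matrix row, in order.
#' @param genes data.frame describing the gene panel: `gene_symbol`,
#'   logical flags `is_susceptibility`, `is_high_confidence`,
#'   `is_autism_predominant`, `is_marker`, and a `categories` column holding
#'   semicolon-separated functional category labels (may be empty). One row
#'   per matrix column, in order.
#' @return an object of class `ExpressionMatrix` with elements `counts`,
#'   `cells`, `genes`.
#' @export
ExpressionMatrix <- function(counts, cells, genes) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  genes <- validate_gene_panel(genes)
  if (nrow(counts) != nrow(cells)) {
    stop("alignment error: counts has ", nrow(counts), " rows but cell table has ",
         nrow(cells), " rows", call. = FALSE)
  }
  if (ncol(counts) != nrow(genes)) {
    stop("alignment error: counts has ", ncol(counts), " columns but panel has ",
         nrow(genes), " genes", call. = FALSE)
  }
  need <- c("cell_id", "x_um", "y_um", "batch_id", "individual_id", "sex",
            "region_label")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("format error: cell table missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("format error: duplicate cell_id values", call. = FALSE)
  }
  if (!all(cells$sex %in% c("M", "F"))) {
    stop("format error: sex must be 'M' or 'F'", call. = FALSE)
  }
  x <- counts@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))) {
    stop("format error: counts must be non-negative integers", call. = FALSE)
  }
  if (!"system_label" %in% names(cells)) cells$system_label <- cells$region_label
  dimnames(counts) <- list(cells$cell_id, genes$gene_symbol)
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "ExpressionMatrix")
}

validate_gene_panel <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "is_susceptibility", "is_high_confidence",
            "is_autism_predominant", "is_marker")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("format error: panel missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_symbol)) {
    stop("format error: duplicate gene symbols in panel", call. = FALSE)
  }
  for (col in need[-1]) genes[[col]] <- as.logical(genes[[col]])
  if (any(genes$is_high_confidence & !genes$is_susceptibility)) {
    stop("format error: high-confidence genes must be susceptibility genes",
         call. = FALSE)
  }
  if (any(genes$is_autism_predominant & !genes$is_susceptibility)) {
    stop("format error: autism-predominant genes must be susceptibility genes",
         call. = FALSE)
  }
  if (!"categories" %in% names(genes)) genes$categories <- ""
  genes$categories[is.na(genes$categories)] <- ""
  cats <- unique(unlist(strsplit(genes$categories[genes$categories != ""], ";",
                                 fixed = TRUE)))
  bad <- setdiff(trimws(cats), PANEL_CATEGORIES)
  if (length(bad)) {
    stop("format error: unknown functional category: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  genes
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  sections:", length(unique(x$cells$batch_id)),
      " regions:", length(unique(x$cells$region_label)),
      " susceptibility genes:", sum(x$genes$is_susceptibility), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Subset an expression matrix by cells and/or genes
#'
#' @param x ExpressionMatrix
#' @param i cell index (integer, logical or cell_id character)
#' @param j gene index (integer, logical or gene_symbol character)
#' @param ... ignored
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$cells$cell_id)
  if (is.character(j)) j <- match(j, x$genes$gene_symbol)
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 cells = x$cells[i, , drop = FALSE],
                 genes = x$genes[j, , drop = FALSE]),
            class = "ExpressionMatrix")
}

#' Read a multi-file spatial dataset
#'
#' The count matrix is matrix-market sparse (`.mtx`) accompanied by two index
#' files, `<matrix>_rows.txt` (cell ids, one per matrix row) and
#' `<matrix>_cols.txt` (gene symbols, one per column). Cell and panel
#' metadata are tab-delimited tables keyed by `cell_id` / `gene_symbol`;
#' both must match the index files exactly (reordering is fine, missing or
#' extra entries are not).
#'
#' @param matrix_path path to the `.mtx` counts file.
#' @param cells_path path to the tab-delimited cell metadata table.
#' @param panel_path path to the tab-delimited gene panel table.
#' @return [ExpressionMatrix()]
#' @export
read_dataset <- function(matrix_path, cells_path, panel_path) {
  counts <- Matrix::readMM(matrix_path)
  stem <- sub("\\.mtx$", "", matrix_path)
  row_ids <- readLines(paste0(stem, "_rows.txt"))
  col_ids <- readLines(paste0(stem, "_cols.txt"))
  if (length(row_ids) != nrow(counts) || length(col_ids) != ncol(counts)) {
    stop("alignment error: index files do not match matrix dimensions",
         call. = FALSE)
  }
  cells <- read_table_tsv(cells_path)
  genes <- read_table_tsv(panel_path)
  if (!setequal(cells$cell_id, row_ids) || nrow(cells) != length(row_ids)) {
    stop("alignment error: cell table does not match matrix rows", call. = FALSE)
  }
  if (!setequal(genes$gene_symbol, col_ids) || nrow(genes) != length(col_ids)) {
    stop("alignment error: panel table does not match matrix columns",
         call. = FALSE)
  }
  cells <- cells[match(row_ids, cells$cell_id), , drop = FALSE]
  genes <- genes[match(col_ids, genes$gene_symbol), , drop = FALSE]
  rownames(cells) <- NULL
  rownames(genes) <- NULL
  ExpressionMatrix(counts, cells, genes)
}

#' Write a spatial dataset to the multi-file exchange format
#'
#' Inverse of [read_dataset()]: writes `<stem>.mtx`, `<stem>_rows.txt`,
#' `<stem>_cols.txt`, plus the cell and panel tables.
#'
#' @param data ExpressionMatrix
#' @param dir output directory (created if absent)
#' @param stem file stem for the matrix files (default "counts")
#' @return named character vector of the five paths written, invisibly.
#' @export
write_dataset <- function(data, dir, stem = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, paste0(stem, ".mtx"))
  Matrix::writeMM(data$counts, mtx)
  writeLines(data$cells$cell_id, file.path(dir, paste0(stem, "_rows.txt")))
  writeLines(data$genes$gene_symbol, file.path(dir, paste0(stem, "_cols.txt")))
  cells_path <- file.path(dir, "cells.tsv")
  panel_path <- file.path(dir, "panel.tsv")
  write_table(data$cells, cells_path)
  write_table(data$genes, panel_path)
  invisible(c(matrix = mtx, cells = cells_path, panel = panel_path,
              rows = file.path(dir, paste0(stem, "_rows.txt")),
              cols = file.path(dir, paste0(stem, "_cols.txt"))))
}

#' Write a result table as tab-delimited text
#'
#' Reals are written with 15 significant digits so a read-back reproduces
#' integers bit-exactly and reals to at least 12 significant digits.
#'
#' @param table data.frame (or an object with an `as.data.frame` method).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, trim = TRUE)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_table()]
#'
#' Columns are type-converted conservatively: full-word `TRUE`/`FALSE`
#' become logical, numeric-looking columns become numeric, everything else
#' stays character (so single-letter codes like sex `F` survive).
#'
#' @param path input path
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = "NA", quote = "", comment.char = "",
                          check.names = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (all(v[ok] %in% c("TRUE", "FALSE"))) {
      df[[j]] <- as.logical(v)
    } else if (all(grepl("^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|Inf|NaN)$",
                         v[ok]))) {
      num <- as.numeric(v)
      int_like <- all(!ok | (grepl("^[+-]?[0-9]+$", v) &
                               abs(num) < .Machine$integer.max), na.rm = TRUE)
      df[[j]] <- if (int_like) as.integer(num) else num
    }
  }
  df
}

#' Read a region vocabulary from YAML
#'
#' The vocabulary maps fine region labels to coarse system labels (e.g.
#' `thalamus`, `germinal zones`). Supplied as a YAML mapping
#' `region_label: system_label`.
#'
#' @param path YAML file path
#' @return named character vector, names = region labels, values = systems
#' @export
read_region_vocabulary <- function(path) {
  v <- yaml::read_yaml(path)
  out <- vapply(v, as.character, character(1))
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("format error: region vocabulary must be a named mapping", call. = FALSE)
  }
  out
}

# Split a semicolon-separated categories column into a named list of
# character vectors per gene.
panel_category_list <- function(genes) {
  out <- lapply(genes$categories, function(s) {
    if (is.na(s) || s == "") character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  names(out) <- genes$gene_symbol
  out
}
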