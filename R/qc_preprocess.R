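#' Remove cells with implausibly high transcript totals
#'
#' Cells whose total transcript count exceeds `max_transcripts` are removed
#' as putative doublets (default ceiling 1000 counts).
#'
#' @param data ExpressionMatrix
#' @param max_transcripts retain cells with total counts `<=` this value.
#' @return list with `data` (filtered ExpressionMatrix) and `report`
#'   (class `QcReport`: `n_cells_in`, `n_cells_removed_high_count`,
#'   `max_transcripts`).
#' @export
filter_cells <- function(data, max_transcripts = 1000) {
  stopifnot(inherits(data, "ExpressionMatrix"), max_transcripts > 0)
  totals <- Matrix::rowSums(data$counts)
  keep <- totals <= max_transcripts
  if (!any(keep)) {
    stop("empty-result error: all ", length(keep),
         " cells exceed the transcript ceiling", call. = FALSE)
  }
  report <- structure(list(n_cells_in = length(keep),
                           n_cells_removed_high_count = sum(!keep),
                           max_transcripts = max_transcripts),
                      class = "QcReport")
  list(data = data[keep, ], report = report)
}

#' @export
as.data.frame.QcReport <- function(x, ...) {
  data.frame(n_cells_in = x$n_cells_in,
             n_cells_removed_high_count = x$n_cells_removed_high_count,
             max_transcripts = x$max_transcripts)
}

#' Per-cell total-count normalization followed by ln(x+1)
#'
#' Each cell with nonzero counts is scaled to `target_sum` total counts,
#' then transformed elementwise with `log1p`. All-zero cells are passed
#' through as zeros with a warning. Used for display-style analyses; the
#' factorization itself consumes raw counts.
#'
#' @param data ExpressionMatrix
#' @param target_sum per-cell total after scaling (default 1000).
#' @return dense numeric matrix, cells x genes, dimnames preserved.
#' @export
normalize_log1p <- function(data, target_sum = 1000) {
  stopifnot(inherits(data, "ExpressionMatrix"), target_sum > 0)
  totals <- Matrix::rowSums(data$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) passed through unnormalized")
  }
  scale <- ifelse(zero, 0, target_sum / totals)
  out <- as.matrix(data$counts * scale)
  log1p(out)
}

#' Number of detected genes per cell over a gene mask
#'
#' A gene is "detected" in a cell when its raw count is at least 1. Used
#' with the susceptibility-gene mask for the regional detection GLM.
#'
#' @param data ExpressionMatrix
#' @param gene_mask logical vector over genes, gene symbols, or column
#'   indices; defaults to the panel's susceptibility genes.
#' @return integer vector, one entry per cell, in `[0, |mask|]`.
#' @export
detection_counts <- function(data, gene_mask = NULL) {
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (is.null(gene_mask)) gene_mask <- data$genes$is_susceptibility
  if (is.logical(gene_mask)) gene_mask <- which(gene_mask)
  if (is.character(gene_mask)) gene_mask <- match(gene_mask, data$genes$gene_symbol)
  if (length(gene_mask) == 0) {
    stop("config error: gene mask is empty", call. = FALSE)
  }
  sub <- data$counts[, gene_mask, drop = FALSE]
  as.integer(Matrix::rowSums(sub >= 1))
}
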