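# Per-region mean of l_c * W_cf for every factor (regions x factors), plus
# the per-region mean ambient background per gene (regions x genes).
region_means_components <- function(model, cells, regions = NULL) {
  stopifnot(inherits(model, "FactorModel"))
  region <- cells$region_label[match(model$cell_ids, cells$cell_id)]
  if (anyNA(region)) stop("alignment error: model cells missing from cell table",
                          call. = FALSE)
  if (is.null(regions)) regions <- sort(unique(region))
  present <- regions %in% region
  if (!all(present)) {
    warning("omitting region(s) with no cells: ",
            paste(regions[!present], collapse = ", "))
    regions <- regions[present]
  }
  lW <- model$W * model$l
  grp <- factor(region, levels = regions)
  keep <- !is.na(grp)
  A <- rowsum(lW[keep, , drop = FALSE], grp[keep]) /
    as.vector(table(grp[keep]))
  lS <- model$S[model$batch_index, , drop = FALSE] * model$l
  Bg <- rowsum(lS[keep, , drop = FALSE], grp[keep]) /
    as.vector(table(grp[keep]))
  list(regions = regions, A = A, Bg = Bg, region_of_cell = region)
}

#' Regional summary of factor activity
#'
#' For every region and factor: the mean reconstructed counts per cell
#' attributable to the factor (summed over genes), and that factor's
#' proportion of total reconstructed expression (factors plus ambient
#' background row-normalize to 1 per region). The mean observed counts per
#' cell per region are reported alongside.
#'
#' @param model fitted FactorModel.
#' @param data ExpressionMatrix carrying the cell table (and observed counts).
#' @param regions optional region vocabulary fixing the rows; regions without
#'   cells are omitted with a warning.
#' @return `RegionFactorSummary`: list with `mean_counts` (regions x
#'   (factors + background)), `proportions` (same shape, rows sum to 1) and
#'   `observed_mean_counts` (per region, over the modeled genes).
#' @export
region_factor_summary <- function(model, data, regions = NULL) {
  rc <- region_means_components(model, data$cells, regions)
  hg <- rowSums(model$H)                                   # per-factor gene sum
  mean_counts <- sweep(rc$A, 2, hg, "*")
  background <- rowSums(rc$Bg)
  mean_counts <- cbind(mean_counts, background = background)
  colnames(mean_counts) <- c(paste0("factor", seq_len(ncol(model$W))),
                             "background")
  rownames(mean_counts) <- rc$regions
  proportions <- mean_counts / rowSums(mean_counts)
  gidx <- match(model$gene_symbols, data$genes$gene_symbol)
  cidx <- match(model$cell_ids, data$cells$cell_id)
  totals <- Matrix::rowSums(data$counts[cidx, gidx, drop = FALSE])
  obs <- tapply(totals, factor(rc$region_of_cell, levels = rc$regions), mean)
  structure(list(mean_counts = mean_counts, proportions = proportions,
                 observed_mean_counts = as.numeric(obs)),
            class = "RegionFactorSummary")
}

#' Relative gene loadings with enrichment and robustness flags
#'
#' For each gene, the mean reconstructed counts attributable to each factor
#' (and to ambient background) are computed per region, averaged across
#' regions unweighted, and normalized: the relative loading of gene `g` on
#' factor `f` is the share of the gene's region-averaged reconstructed
#' expression explained by that factor. Genes are flagged factor-enriched
#' where the relative loading exceeds `enrichment_threshold` (default 33%),
#' and robustly expressed where the maximum regional mean observed count
#' reaches `robust_threshold` (typically from
#' [robust_expression_threshold()]).
#'
#' @param model fitted FactorModel.
#' @param data ExpressionMatrix carrying cell metadata and observed counts.
#' @param regions optional region vocabulary for the unweighted average.
#' @param enrichment_threshold relative-loading cutoff for enrichment
#'   (default 0.33, strict `>`).
#' @param robust_threshold minimum max regional mean observed expression;
#'   `NULL` computes it from the data via [robust_expression_threshold()].
#' @param include_background include the ambient term in the denominator
#'   (default TRUE).
#' @return `GeneLoadingTable`: list with `loadings` (genes x factors),
#'   `background_share`, `max_regional_mean`, `enriched` (logical matrix),
#'   `robust` (logical), `assigned_factor` (NA until
#'   [assign_overlapping_genes()]), and thresholds used.
#' @export
relative_gene_loading <- function(model, data, regions = NULL,
                                  enrichment_threshold = 0.33,
                                  robust_threshold = NULL,
                                  include_background = TRUE) {
  rc <- region_means_components(model, data$cells, regions)
  Abar <- colMeans(rc$A)                    # per factor: avg over regions
  fac <- outer(Abar, rep(1, ncol(model$H))) * model$H  # factors x genes
  bg <- colMeans(rc$Bg)                     # per gene
  denom <- colSums(fac) + if (include_background) bg else 0
  loadings <- t(fac) / ifelse(denom > 0, denom, NA)
  background_share <- if (include_background) bg / ifelse(denom > 0, denom, NA)
                      else rep(0, length(bg))
  undefined <- denom <= 0
  if (any(undefined)) loadings[undefined, ] <- NA

  grm <- gene_region_means(data, rc$regions, model)
  max_regional_mean <- apply(grm, 2, max)
  if (is.null(robust_threshold)) {
    robust_threshold <- stats::median(max_regional_mean)
  }
  enriched <- !is.na(loadings) & loadings > enrichment_threshold
  robust <- max_regional_mean >= robust_threshold
  rownames(loadings) <- model$gene_symbols
  colnames(loadings) <- paste0("factor", seq_len(ncol(model$W)))
  dimnames(enriched) <- dimnames(loadings)
  names(background_share) <- model$gene_symbols
  names(max_regional_mean) <- model$gene_symbols
  names(robust) <- model$gene_symbols
  structure(list(loadings = loadings, background_share = background_share,
                 max_regional_mean = max_regional_mean, enriched = enriched,
                 robust = robust,
                 assigned_factor = rep(NA_integer_, nrow(loadings)),
                 enrichment_threshold = enrichment_threshold,
                 robust_threshold = robust_threshold),
            class = "GeneLoadingTable")
}

# Observed mean counts per cell, per region (regions x genes), restricted to
# the model's genes when a model is given.
gene_region_means <- function(data, regions, model = NULL) {
  gidx <- if (is.null(model)) seq_len(ncol(data$counts))
          else match(model$gene_symbols, data$genes$gene_symbol)
  cidx <- if (is.null(model)) seq_len(nrow(data$counts))
          else match(model$cell_ids, data$cells$cell_id)
  region <- data$cells$region_label[cidx]
  keep <- region %in% regions
  X <- data$counts[cidx, gidx, drop = FALSE][keep, , drop = FALSE]
  grp <- factor(region[keep], levels = regions)
  out <- rowsum(as.matrix(X), grp) / as.vector(table(grp))
  colnames(out) <- data$genes$gene_symbol[gidx]
  out
}

#' @export
as.data.frame.GeneLoadingTable <- function(x, ...) {
  g <- rownames(x$loadings); f <- colnames(x$loadings)
  data.frame(
    gene_symbol = rep(g, times = length(f)),
    factor = rep(f, each = length(g)),
    relative_loading = as.vector(x$loadings),
    enriched = as.vector(x$enriched),
    background_share = rep(x$background_share, times = length(f)),
    max_regional_mean = rep(x$max_regional_mean, times = length(f)),
    robust = rep(x$robust, times = length(f)),
    assigned_factor = rep(x$assigned_factor, times = length(f)),
    stringsAsFactors = FALSE)
}

#' Robust-expression threshold from maximum regional mean expression
#'
#' For each gene, mean observed counts per cell are computed in each included
#' region; the per-gene maximum across regions is taken, and the threshold is
#' the median of those maxima across genes.
#'
#' @param data ExpressionMatrix.
#' @param regions character vector of regions to include (e.g. cortical
#'   zones, ganglionic eminences and thalamus).
#' @param genes optional gene selector (defaults to all panel genes).
#' @return the threshold (scalar), with per-gene maxima in
#'   `attr(, "max_regional_mean")`.
#' @export
robust_expression_threshold <- function(data, regions, genes = NULL) {
  if (length(regions) == 0) {
    stop("config error: empty region subset", call. = FALSE)
  }
  if (!any(data$cells$region_label %in% regions)) {
    stop("config error: no cells in the included regions", call. = FALSE)
  }
  sub <- if (is.null(genes)) data else data[, genes]
  grm <- gene_region_means(sub, intersect(sort(unique(sub$cells$region_label)),
                                          regions))
  mx <- apply(grm, 2, max)
  out <- stats::median(mx)
  attr(out, "max_regional_mean") <- mx
  out
}

#' Assign multi-factor-enriched genes to their strongest factor
#'
#' Genes enriched in more than one factor are assigned to the factor with
#' the highest relative loading; ties go to the lowest factor index with a
#' warning. Single-factor-enriched genes keep their factor; unenriched genes
#' stay unassigned.
#'
#' @param table a [relative_gene_loading()] result.
#' @return the table with `assigned_factor` filled in.
#' @export
assign_overlapping_genes <- function(table) {
  stopifnot(inherits(table, "GeneLoadingTable"))
  n_enr <- rowSums(table$enriched)
  assigned <- rep(NA_integer_, nrow(table$loadings))
  for (i in which(n_enr >= 1)) {
    cand <- table$loadings[i, ]
    best <- which(cand == max(cand[table$enriched[i, ]]))
    best <- intersect(best, which(table$enriched[i, ]))
    if (length(best) > 1) {
      warning("gene ", rownames(table$loadings)[i],
              ": tied relative loadings; assigned to factor ", min(best))
    }
    assigned[i] <- min(best)
  }
  table$assigned_factor <- assigned
  table
}

#' Disjoint factor gene sets after overlap assignment
#'
#' @param table GeneLoadingTable after [assign_overlapping_genes()].
#' @param robust_only restrict to robustly expressed genes (default TRUE).
#' @return named list of gene symbol vectors, one per factor with members.
#' @export
factor_gene_sets <- function(table, robust_only = TRUE) {
  keep <- !is.na(table$assigned_factor) & (!robust_only | table$robust)
  split(rownames(table$loadings)[keep],
        colnames(table$loadings)[table$assigned_factor[keep]])
}

#' Functional-category enrichment of a factor's genes
#'
#' Fisher's exact test per category: are genes annotated with the category
#' over-represented in the factor gene set, against the background of all
#' susceptibility genes on the panel?
#'
#' @param genes_in_factor character vector of gene symbols.
#' @param panel gene panel data.frame (with `categories` column).
#' @param background background gene symbols (default: all susceptibility
#'   genes on the panel).
#' @return data.frame: category, counts of the 2x2 table, odds ratio,
#'   two-sided p-value.
#' @export
category_enrichment <- function(genes_in_factor, panel, background = NULL) {
  panel <- validate_gene_panel(panel)
  if (is.null(background)) {
    background <- panel$gene_symbol[panel$is_susceptibility]
  }
  cats <- panel_category_list(panel)
  res <- lapply(PANEL_CATEGORIES, function(cat) {
    in_cat <- names(cats)[vapply(cats, function(v) cat %in% v, logical(1))]
    in_cat <- intersect(in_cat, background)
    if (length(genes_in_factor) == 0 || length(in_cat) == 0) {
      if (length(in_cat) == 0) {
        warning("category '", cat, "' absent from background; returning NA")
      }
      return(data.frame(category = cat, n_factor_cat = NA_integer_,
                        n_factor = length(genes_in_factor),
                        n_background_cat = length(in_cat),
                        n_background = length(background),
                        odds_ratio = NA_real_, p_value = NA_real_))
    }
    gf <- intersect(genes_in_factor, background)
    a <- length(intersect(gf, in_cat))
    b <- length(setdiff(gf, in_cat))
    c <- length(setdiff(in_cat, gf))
    d <- length(background) - a - b - c
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2, 2))
    data.frame(category = cat, n_factor_cat = a, n_factor = length(gf),
               n_background_cat = length(in_cat),
               n_background = length(background),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  do.call(rbind, res)
}
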