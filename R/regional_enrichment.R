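#' Binomial GLM of susceptibility-gene detection per cell
#'
#' Models the number of detected susceptibility genes per cell (out of
#' `n_trials` panel genes) with a logit-link binomial GLM with region and
#' sex covariates. Regions use deviation (sum-to-zero) coding, so each
#' region's coefficient is its log-odds deviation from the across-region
#' average; the test per region is a Wald test of that deviation (two-sided
#' p stored, direction reported), with Benjamini-Hochberg FDR across
#' regions.
#'
#' @param detections integer vector of per-cell detected gene counts.
#' @param n_trials number of genes in the detection panel (constant trials).
#' @param cells data.frame with `region_label` and `sex` per cell.
#' @param min_cells regions with fewer cells are excluded with a warning
#'   (default 50).
#' @return `GlmResult`: list with `regions` data.frame (region, estimate,
#'   std_error, p_value, q_value, direction, n_cells), `sex` data.frame (or
#'   NULL when sex is constant), `n_cells`, `n_trials`, `separation` flag.
#' @export
fit_detection_glm <- function(detections, n_trials, cells, min_cells = 50) {
  stopifnot(length(detections) == nrow(cells),
            all(detections >= 0), all(detections <= n_trials))
  region <- as.character(cells$region_label)
  sex <- as.character(cells$sex)
  tab <- table(region)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("excluding region(s) with fewer than ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !(region %in% small)
    detections <- detections[keep]; region <- region[keep]; sex <- sex[keep]
  }
  levs <- sort(unique(region))
  if (length(levs) < 2) {
    stop("config error: need at least two regions after exclusion",
         call. = FALSE)
  }
  # aggregate cells sharing covariates: identical binomial likelihood
  agg <- stats::aggregate(cbind(det = detections) ~ region + sex,
                          FUN = sum)
  agg$n <- stats::aggregate(detections ~ region + sex, FUN = length)$detections
  agg$fail <- agg$n * n_trials - agg$det
  agg$region <- factor(agg$region, levels = levs)
  use_sex <- length(unique(sex)) > 1
  form <- if (use_sex) cbind(det, fail) ~ region + sex else cbind(det, fail) ~ region
  fit <- stats::glm(form, family = stats::binomial(), data = agg,
                    contrasts = list(region = "contr.sum"))
  separation <- any(fit$fitted.values %in% c(0, 1)) ||
    any(sqrt(diag(stats::vcov(fit))) > 10)
  if (separation) {
    warning("possible separation; refitting with Jeffreys-style augmentation")
    agg$det <- agg$det + 0.5
    agg$fail <- agg$fail + 0.5
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = agg,
                                       contrasts = list(region = "contr.sum")))
  }
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  K <- length(levs)
  ridx <- grep("^region", names(co))
  est <- numeric(K); se <- numeric(K)
  for (k in seq_len(K)) {
    # contrast vector picking region k's deviation from the grand mean
    cv <- numeric(length(co))
    if (k < K) cv[ridx[k]] <- 1 else cv[ridx] <- -1
    est[k] <- sum(cv * co)
    se[k] <- sqrt(drop(t(cv) %*% V %*% cv))
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  regions_df <- data.frame(
    region = levs, estimate = est, std_error = se, p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    direction = ifelse(est > 0, "above", "below"),
    n_cells = as.integer(tab[levs]), stringsAsFactors = FALSE)
  sex_df <- NULL
  if (use_sex) {
    sidx <- grep("^sex", names(co))
    sex_df <- data.frame(term = names(co)[sidx], estimate = co[sidx],
                         std_error = sqrt(diag(V))[sidx],
                         p_value = 2 * stats::pnorm(-abs(co[sidx] /
                                                         sqrt(diag(V))[sidx])),
                         row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(regions = regions_df, sex = sex_df,
                 n_cells = length(detections), n_trials = n_trials,
                 separation = separation, fit = fit),
            class = "GlmResult")
}

#' Regional marker genes by rank-sum test with stratified subsampling
#'
#' Each region is capped at `per_region_cap` cells, drawn evenly across
#' tissue sections (seeded); the Wilcoxon rank-sum test then compares raw
#' counts per gene between each region and the rest of the subsampled
#' dataset, with Benjamini-Hochberg adjustment across genes within each
#' region.
#'
#' @param data ExpressionMatrix.
#' @param per_region_cap maximum cells per region (default 25000).
#' @param seed RNG seed for the subsample.
#' @param genes optional gene selector.
#' @param alpha significance level on adjusted p-values (default 0.05);
#'   markers satisfy `p_adj < alpha` (`comparator = "below"`), the
#'   comparator being configurable.
#' @param comparator `"below"` (default) or `"above"`.
#' @return `DeResult`: list with `table` (region, gene, statistic, p_value,
#'   p_adj, direction, is_marker), `subsample_sizes`, `cap`, `seed`.
#' @export
rank_sum_regional_de <- function(data, per_region_cap = 25000, seed = 1,
                                 genes = NULL, alpha = 0.05,
                                 comparator = c("below", "above")) {
  comparator <- match.arg(comparator)
  sub <- if (is.null(genes)) data else data[, genes]
  region <- sub$cells$region_label
  levs <- sort(unique(region))
  if (length(levs) < 2) stop("config error: need at least two regions",
                             call. = FALSE)
  set.seed(seed)
  picked <- integer(0)
  sizes <- stats::setNames(integer(length(levs)), levs)
  for (r in levs) {
    # deterministic given seed: iterate regions in sorted order
    idx <- which(region == r)
    if (length(idx) <= per_region_cap) {
      sel <- idx
    } else {
      secs <- sub$cells$batch_id[idx]
      sl <- sort(unique(secs))
      quota <- rep(per_region_cap %/% length(sl), length(sl))
      extra <- per_region_cap - sum(quota)
      if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
      sel <- integer(0)
      for (k in seq_along(sl)) {
        pool <- idx[secs == sl[k]]
        take <- min(length(pool), quota[k])
        sel <- c(sel, if (length(pool) == 1) pool else sample(pool, take))
      }
      # top up from the remainder if some sections ran short
      short <- per_region_cap - length(sel)
      if (short > 0) {
        pool <- setdiff(idx, sel)
        sel <- c(sel, sample(pool, min(short, length(pool))))
      }
    }
    sizes[r] <- length(sel)
    picked <- c(picked, sel)
  }
  picked <- sort(picked)
  X <- as.matrix(sub$counts[picked, , drop = FALSE])
  reg <- region[picked]
  res <- list()
  for (r in levs) {
    ingrp <- reg == r
    stat <- numeric(ncol(X)); pv <- numeric(ncol(X)); dir <- character(ncol(X))
    for (j in seq_len(ncol(X))) {
      wt <- stats::wilcox.test(X[ingrp, j], X[!ingrp, j], exact = FALSE)
      stat[j] <- unname(wt$statistic)
      pv[j] <- wt$p.value
      dir[j] <- if (mean(rank(X[, j])[ingrp]) >= mean(rank(X[, j])[!ingrp]))
        "up" else "down"
    }
    padj <- stats::p.adjust(pv, method = "BH")
    res[[r]] <- data.frame(region = r, gene = sub$genes$gene_symbol,
                           statistic = stat, p_value = pv, p_adj = padj,
                           direction = dir, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, c(res, make.row.names = FALSE))
  table$is_marker <- if (comparator == "below") table$p_adj < alpha
                     else table$p_adj > alpha
  structure(list(table = table, subsample_sizes = sizes,
                 cap = per_region_cap, seed = seed),
            class = "DeResult")
}

#' Rank regions by mean susceptibility-gene detection per cell per individual
#'
#' @param detections per-cell detected gene counts.
#' @param cells data.frame with `region_label` and `individual_id`.
#' @return list with `per_individual` (region x individual matrix of mean
#'   detections) and `summary` data.frame (region, mean_detected, rank;
#'   rank 1 = highest), ordered by rank.
#' @export
rank_regions_by_detection <- function(detections, cells) {
  stopifnot(length(detections) == nrow(cells),
            "individual_id" %in% names(cells))
  grp_r <- factor(cells$region_label)
  grp_i <- factor(cells$individual_id)
  M <- tapply(detections, list(grp_r, grp_i), mean)
  avg <- rowMeans(M, na.rm = TRUE)
  summary <- data.frame(region = names(avg), mean_detected = unname(avg),
                        stringsAsFactors = FALSE)
  summary$rank <- rank(-summary$mean_detected, ties.method = "min")
  summary <- summary[order(summary$rank), ]
  rownames(summary) <- NULL
  list(per_individual = M, summary = summary)
}
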