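#' Configure a synthetic multi-section spatial dataset
#'
#' The generator runs the factor model forward: cell loadings `W` are
#' Gamma-distributed with a high mean on each region's dominant factor and a
#' low mean elsewhere; gene loadings `H` are sparse with distinct support per
#' factor; per-cell detection efficiency `l` is log-normal with mean 1 per
#' section; ambient background `S` is exponential per section x gene; counts
#' are Negative Binomial around the model mean. Spatial coordinates are laid
#' out as one block per region per section — cosmetic only, the model never
#' reads them.
#'
#' @param n_cells_per_region cells simulated per region (split across sections).
#' @param regions character vector of region labels.
#' @param n_factors_true number of generative factors; must not exceed the
#'   number of regions. Regions are assigned dominant factors round-robin.
#' @param n_genes panel size.
#' @param n_batches number of tissue sections.
#' @param efficiency_sd standard deviation of log detection efficiency.
#' @param background_rate mean ambient background, counts per gene per cell.
#' @param dispersion scale of the per-gene NB concentration `a_g`
#'   (larger = closer to Poisson).
#' @param seed integer RNG seed.
#' @param loading_high,loading_low mean cell loading on the dominant /
#'   non-dominant factors.
#' @param gene_loading_mean mean gene loading on a factor's support genes.
#' @param frac_susceptibility fraction of panel genes flagged as autism
#'   susceptibility genes (the factorization input set).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_cells_per_region = 2000,
                              regions = c("thalamus", "germinal zones",
                                          "cortical plate", "subplate",
                                          "putamen"),
                              n_factors_true = 5,
                              n_genes = 100,
                              n_batches = 3,
                              efficiency_sd = 0.3,
                              background_rate = 0.05,
                              dispersion = 2,
                              seed = 1,
                              loading_high = 1,
                              loading_low = 0.03,
                              gene_loading_mean = 2.5,
                              frac_susceptibility = 0.8) {
  if (n_cells_per_region < 1 || n_genes < 1) {
    stop("config error: need at least one cell per region and one gene",
         call. = FALSE)
  }
  if (n_factors_true > length(regions)) {
    stop("config error: n_factors_true exceeds number of regions", call. = FALSE)
  }
  if (efficiency_sd <= 0 || dispersion <= 0 || background_rate < 0) {
    stop("config error: scales must be positive (background_rate may be 0)",
         call. = FALSE)
  }
  structure(list(n_cells_per_region = n_cells_per_region, regions = regions,
                 n_factors_true = n_factors_true, n_genes = n_genes,
                 n_batches = n_batches, efficiency_sd = efficiency_sd,
                 background_rate = background_rate, dispersion = dispersion,
                 seed = seed, loading_high = loading_high,
                 loading_low = loading_low,
                 gene_loading_mean = gene_loading_mean,
                 frac_susceptibility = frac_susceptibility),
            class = "SimulationConfig")
}

#' Simulate a multi-section spatial count dataset with known ground truth
#'
#' Draws every parameter of the factor model, then samples counts
#' `X_cg ~ NB(mean = l_c (S_eg + sum_f W_cf H_fg), concentration = a_g)`
#' through the same mean function the fitted model uses, so the simulation
#' and inference means cannot drift apart.
#'
#' @param config a [simulation_config()].
#' @return list with `data` (an [ExpressionMatrix()]) and `truth` (class
#'   `GroundTruth`: `W`, `H`, `l`, `S`, `a`, `region_factor`, the
#'   region-to-dominant-factor map).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  R <- length(config$regions)
  Ft <- config$n_factors_true
  G <- config$n_genes
  E <- config$n_batches
  n <- config$n_cells_per_region * R

  region_factor <- stats::setNames(rep(seq_len(Ft), length.out = R),
                                   config$regions)
  region <- rep(config$regions, each = config$n_cells_per_region)
  batch <- paste0("section", rep_len(seq_len(E), config$n_cells_per_region))
  batch <- rep(sample(batch), R)                       # sections within region
  sec_levels <- paste0("section", seq_len(E))
  ind_of_sec <- stats::setNames(paste0("ind", ((seq_len(E) - 1L) %/% 2L) + 1L),
                                sec_levels)
  sex_of_ind <- stats::setNames(
    rep(c("F", "M"), length.out = length(unique(ind_of_sec))),
    unique(ind_of_sec))

  # cell loadings: dominant factor high, others low
  shape_hi <- 10; shape_lo <- 2
  W <- matrix(stats::rgamma(n * Ft, shape = shape_lo,
                            rate = shape_lo / config$loading_low), n, Ft)
  dom <- region_factor[region]
  idx <- cbind(seq_len(n), dom)
  W[idx] <- stats::rgamma(n, shape = shape_hi,
                          rate = shape_hi / config$loading_high)

  # gene loadings: each gene has one primary factor (round-robin), a minority
  # also carry a weak secondary loading
  H <- matrix(0, Ft, G)
  primary <- rep_len(seq_len(Ft), G)
  H[cbind(primary, seq_len(G))] <- stats::rgamma(
    G, shape = 4, rate = 4 / config$gene_loading_mean)
  secondary <- stats::runif(G) < 0.15
  if (any(secondary)) {
    f2 <- vapply(primary[secondary], function(f) {
      sample(setdiff(seq_len(Ft), f), 1L)
    }, integer(1))
    H[cbind(f2, which(secondary))] <- stats::rgamma(
      sum(secondary), shape = 2, rate = 2 / (0.2 * config$gene_loading_mean))
  }

  # detection efficiency, mean 1 per section
  l <- stats::rlnorm(n, meanlog = 0, sdlog = config$efficiency_sd)
  for (e in sec_levels) {
    sel <- batch == e
    if (any(sel)) l[sel] <- l[sel] / mean(l[sel])
  }

  S <- matrix(if (config$background_rate > 0) {
    stats::rexp(E * G, rate = 1 / config$background_rate)
  } else 0, E, G, dimnames = list(sec_levels, NULL))

  a <- stats::rlnorm(G, meanlog = log(config$dispersion), sdlog = 0.3)

  batch_idx <- match(batch, sec_levels)
  mu <- nmf_mean_matrix(W, H, l, S, batch_idx)
  counts <- matrix(stats::rnbinom(n * G, size = rep(a, each = n), mu = mu),
                   n, G)

  # block layout: one 1000x1000 um tile per region, per section
  rx <- (match(region, config$regions) - 1L) %% 3L
  ry <- (match(region, config$regions) - 1L) %/% 3L
  cells <- data.frame(
    cell_id = sprintf("cell%06d", seq_len(n)),
    x_um = rx * 1000 + stats::runif(n, 0, 900),
    y_um = ry * 1000 + stats::runif(n, 0, 900),
    batch_id = batch,
    individual_id = unname(ind_of_sec[batch]),
    sex = unname(sex_of_ind[ind_of_sec[batch]]),
    region_label = region,
    system_label = region,
    stringsAsFactors = FALSE)

  n_sus <- max(1L, round(config$frac_susceptibility * G))
  is_sus <- seq_len(G) <= n_sus
  hi_conf <- is_sus & stats::runif(G) < 0.4
  genes <- data.frame(
    gene_symbol = sprintf("GENE%03d", seq_len(G)),
    is_susceptibility = is_sus,
    is_high_confidence = hi_conf,
    is_autism_predominant = is_sus & !hi_conf & stats::runif(G) < 0.15,
    is_marker = !is_sus,
    categories = ifelse(stats::runif(G) < 0.5,
                        sample(PANEL_CATEGORIES, G, replace = TRUE), ""),
    stringsAsFactors = FALSE)

  data <- ExpressionMatrix(counts, cells, genes)
  truth <- structure(list(W = W, H = H, l = l, S = S, a = a,
                          batch_index = batch_idx,
                          region_factor = region_factor),
                     class = "GroundTruth")
  list(data = data, truth = truth)
}

#' Simulate a de novo mutation cohort over disjoint gene sets
#'
#' Observed protein-truncating DNM counts per gene are Poisson with mean
#' `2 * n_probands * rate_g * enrichment_{set(g)}` (two haploid genomes per
#' proband).
#'
#' @param gene_sets named list of character vectors; the sets must be
#'   disjoint (overlapping genes are resolved upstream, see
#'   [assign_overlapping_genes()]).
#' @param rates named numeric vector of per-gene haploid PTV mutation rates.
#' @param n_probands cohort size.
#' @param enrichment named numeric vector, fold enrichment per set (default 1).
#' @param seed integer RNG seed.
#' @param cohort_id,phenotype cohort annotations.
#' @return a `DnmCohort` list: `cohort_id`, `phenotype`, `n_probands`,
#'   `counts` (named per-gene observed counts), `rates`, `gene_sets`.
#' @export
simulate_dnm_cohort <- function(gene_sets, rates, n_probands,
                                enrichment = NULL, seed = 1,
                                cohort_id = "synthetic", phenotype = "autism") {
  all_genes <- unlist(gene_sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("config error: gene sets must be disjoint; overlapping gene(s): ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(all_genes %in% names(rates))) {
    stop("data error: missing mutation rate for gene(s): ",
         paste(setdiff(all_genes, names(rates)), collapse = ", "),
         call. = FALSE)
  }
  if (any(rates[all_genes] <= 0)) {
    stop("data error: mutation rates must be positive", call. = FALSE)
  }
  if (is.null(enrichment)) {
    enrichment <- stats::setNames(rep(1, length(gene_sets)), names(gene_sets))
  }
  if (any(enrichment < 0)) {
    stop("config error: enrichment must be non-negative", call. = FALSE)
  }
  set_of <- rep(names(gene_sets), lengths(gene_sets))
  names(set_of) <- all_genes
  set.seed(seed)
  lam <- 2 * n_probands * rates[all_genes] * enrichment[set_of[all_genes]]
  counts <- stats::setNames(stats::rpois(length(all_genes), lam), all_genes)
  dnm_cohort(cohort_id = cohort_id, phenotype = phenotype,
             n_probands = n_probands, counts = counts,
             rates = rates[all_genes], gene_sets = gene_sets)
}

#' Construct a DNM cohort object
#'
#' @param cohort_id cohort label.
#' @param phenotype `"autism"` or `"DD"`.
#' @param n_probands number of probands.
#' @param counts named non-negative integer vector of observed PTV DNM
#'   counts per gene.
#' @param rates named positive numeric vector of haploid PTV mutation rates.
#' @param gene_sets optional named list of disjoint gene sets.
#' @export
dnm_cohort <- function(cohort_id, phenotype = c("autism", "DD"), n_probands,
                       counts, rates, gene_sets = NULL) {
  phenotype <- match.arg(phenotype)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("data error: observed DNM counts must be non-negative integers",
         call. = FALSE)
  }
  if (!all(names(counts) %in% names(rates))) {
    stop("data error: missing mutation rate for gene(s): ",
         paste(setdiff(names(counts), names(rates)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(cohort_id = cohort_id, phenotype = phenotype,
                 n_probands = as.integer(n_probands), counts = counts,
                 rates = rates, gene_sets = gene_sets),
            class = "DnmCohort")
}
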