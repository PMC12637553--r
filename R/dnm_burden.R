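#' Expected de novo mutation count for a gene set
#'
#' Two haploid genomes per proband:
#' `expected = 2 * n_probands * sum_g rate_g`.
#'
#' @param genes character vector of gene symbols.
#' @param rates named per-gene haploid PTV mutation rates.
#' @param n_probands cohort size.
#' @return expected count (scalar).
#' @export
expected_dnm_count <- function(genes, rates, n_probands) {
  if (length(genes) == 0) {
    warning("empty gene set; expected count is 0")
    return(0)
  }
  missing <- setdiff(genes, names(rates))
  if (length(missing)) {
    stop("data error: missing mutation rate for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  2 * n_probands * sum(rates[genes])
}

#' Observed vs expected DNM burden of a gene set
#'
#' Observed counts are summed over the set; the observed/expected ratio
#' carries an exact (Garwood) Poisson 95% CI on the observed count. The
#' average burden per gene per child is `observed / (|genes| * n_probands)`.
#'
#' @param cohort a `DnmCohort`.
#' @param genes character vector of gene symbols in the set.
#' @return data.frame: observed, expected, oe (ratio), oe_lo, oe_hi (95% CI),
#'   per_gene_per_child, n_genes.
#' @export
set_burden <- function(cohort, genes) {
  stopifnot(inherits(cohort, "DnmCohort"))
  expected <- expected_dnm_count(genes, cohort$rates, cohort$n_probands)
  observed <- sum(cohort$counts[intersect(genes, names(cohort$counts))])
  ci <- garwood_ci(observed)
  data.frame(observed = observed, expected = expected,
             oe = if (expected > 0) observed / expected else NA_real_,
             oe_lo = if (expected > 0) ci[1] / expected else NA_real_,
             oe_hi = if (expected > 0) ci[2] / expected else NA_real_,
             per_gene_per_child = if (length(genes) > 0)
               observed / (length(genes) * cohort$n_probands) else NA_real_,
             n_genes = length(genes))
}

# Exact Poisson CI on a count (Garwood, via chi-square quantiles).
garwood_ci <- function(x, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qchisq(a, 2 * x) / 2
  hi <- stats::qchisq(1 - a, 2 * (x + 1)) / 2
  c(lo, hi)
}

#' Relative risk between two gene sets' DNM burdens
#'
#' The relative risk is the ratio of observed/expected ratios,
#' `RR = (obs_A/exp_A) / (obs_B/exp_B)`. Conditional on the total
#' `obs_A + obs_B`, `obs_A` is Binomial with success probability
#' `exp_A/(exp_A+exp_B)` under the null of equal enrichment (the exact
#' conditional comparison of two Poisson rates); the two-sided p doubles the
#' smaller tail (capped at 1), and the 95% CI inverts the conditional
#' binomial (Clopper-Pearson).
#'
#' @param cohort a `DnmCohort`.
#' @param set_A,set_B disjoint gene sets (symbol vectors).
#' @param conf confidence level (default 0.95).
#' @return data.frame: obs_A, exp_A, obs_B, exp_B, rr, rr_lo, rr_hi, p_value.
#' @export
pairwise_relative_risk <- function(cohort, set_A, set_B, conf = 0.95) {
  if (length(intersect(set_A, set_B))) {
    stop("config error: gene sets must be disjoint", call. = FALSE)
  }
  bA <- set_burden(cohort, set_A)
  bB <- set_burden(cohort, set_B)
  oA <- bA$observed; oB <- bB$observed
  eA <- bA$expected; eB <- bB$expected
  n <- oA + oB
  if (n == 0) {
    return(data.frame(obs_A = oA, exp_A = eA, obs_B = oB, exp_B = eB,
                      rr = NA_real_, rr_lo = NA_real_, rr_hi = NA_real_,
                      p_value = 1))
  }
  p0 <- eA / (eA + eB)
  p <- poisson_ratio_p(oA, n, p0)
  rr <- if (oB > 0) (oA / eA) / (oB / eB) else Inf
  a <- (1 - conf) / 2
  p_lo <- if (oA == 0) 0 else stats::qbeta(a, oA, oB + 1)
  p_hi <- if (oB == 0) 1 else stats::qbeta(1 - a, oA + 1, oB)
  to_rr <- function(pp) if (pp >= 1) Inf else (pp / (1 - pp)) * (eB / eA)
  data.frame(obs_A = oA, exp_A = eA, obs_B = oB, exp_B = eB,
             rr = rr, rr_lo = to_rr(p_lo), rr_hi = to_rr(p_hi), p_value = p)
}

# Two-sided exact conditional p by doubling the smaller binomial tail.
poisson_ratio_p <- function(x, n, p0) {
  lower <- stats::pbinom(x, n, p0)
  upper <- 1 - stats::pbinom(x - 1, n, p0)
  min(1, 2 * min(lower, upper))
}

#' All pairwise relative risks between disjoint gene sets, with Bonferroni
#'
#' @param cohort a `DnmCohort`.
#' @param gene_sets named list of disjoint gene sets (default: the cohort's
#'   own sets).
#' @return `BurdenResult`: list with `burden` (per-set [set_burden()] rows)
#'   and `pairs` (per ordered pair A over B: RR, CI, p, Bonferroni-adjusted
#'   p and significance at 0.05).
#' @export
dnm_burden_test <- function(cohort, gene_sets = cohort$gene_sets) {
  stopifnot(inherits(cohort, "DnmCohort"), !is.null(gene_sets))
  burden <- do.call(rbind, lapply(names(gene_sets), function(s) {
    cbind(gene_set = s, set_burden(cohort, gene_sets[[s]]))
  }))
  nm <- names(gene_sets)
  pairs <- if (length(nm) >= 2) {
    cmb <- utils::combn(nm, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      cbind(set_A = a, set_B = b,
            pairwise_relative_risk(cohort, gene_sets[[a]], gene_sets[[b]]))
    }))
  } else NULL
  if (!is.null(pairs)) {
    pairs$p_bonferroni <- pmin(1, pairs$p_value * nrow(pairs))
    pairs$significant <- pairs$p_bonferroni < 0.05
  }
  structure(list(cohort_id = cohort$cohort_id, phenotype = cohort$phenotype,
                 burden = burden, pairs = pairs),
            class = "BurdenResult")
}

#' Read a DNM cohort table
#'
#' Tab-delimited columns: gene, cohort_id, phenotype, observed_count,
#' mutation_rate, n_probands. One cohort per file.
#'
#' @param path input TSV.
#' @param gene_sets optional named list of disjoint gene sets.
#' @return `DnmCohort`.
#' @export
read_dnm_cohort <- function(path, gene_sets = NULL) {
  df <- read_table_tsv(path)
  need <- c("gene", "cohort_id", "phenotype", "observed_count",
            "mutation_rate", "n_probands")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: cohort table missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(df$cohort_id)) != 1) {
    stop("format error: one cohort per file", call. = FALSE)
  }
  dnm_cohort(cohort_id = df$cohort_id[1], phenotype = df$phenotype[1],
             n_probands = df$n_probands[1],
             counts = stats::setNames(df$observed_count, df$gene),
             rates = stats::setNames(df$mutation_rate, df$gene),
             gene_sets = gene_sets)
}
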