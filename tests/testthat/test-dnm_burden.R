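test_that("expected DNM counts follow the diploid rate sum", {
  rates <- c(g1 = 1e-5, g2 = 3e-5)
  expect_equal(expected_dnm_count(c("g1", "g2"), rates, 10000), 0.8)
  expect_warning(e0 <- expected_dnm_count(character(0), rates, 10000), "empty")
  expect_equal(e0, 0)
  expect_error(expected_dnm_count(c("g1", "gX"), rates, 10), "gX")
  # brute-force oracle on a 50-gene set
  set.seed(8)
  r50 <- stats::setNames(runif(50, 1e-6, 1e-4), paste0("g", 1:50))
  brute <- 0
  for (g in names(r50)) brute <- brute + 2 * 7777 * r50[[g]]
  expect_equal(expected_dnm_count(names(r50), r50, 7777), brute,
               tolerance = 1e-12)
})

test_that("set burden reports O/E with an exact Poisson interval", {
  rates <- stats::setNames(rep(5e-5, 5), paste0("g", 1:5))
  counts <- stats::setNames(c(3L, 2L, 0L, 4L, 1L), paste0("g", 1:5))
  ch <- dnm_cohort("c1", "autism", 10000, counts, rates)
  b <- set_burden(ch, paste0("g", 1:5))
  expect_equal(b$observed, 10)
  expect_equal(b$expected, 2 * 10000 * 5 * 5e-5)
  expect_equal(b$oe, 2)
  expect_equal(b$per_gene_per_child, 10 / (5 * 10000))
  # Garwood bounds agree with direct Poisson tail summation at the bound
  lo <- b$oe_lo * b$expected; hi <- b$oe_hi * b$expected
  expect_equal(1 - ppois(10 - 1, lo), 0.025, tolerance = 1e-6)
  expect_equal(ppois(10, hi), 0.025, tolerance = 1e-6)
  # observed 0 is degenerate with a zero lower bound
  b0 <- set_burden(dnm_cohort("c", "DD", 100,
                              c(g1 = 0L), c(g1 = 1e-5)), "g1")
  expect_equal(b0$oe, 0)
  expect_equal(b0$oe_lo, 0)
  expect_gt(b0$oe_hi, 0)
})

test_that("burden is additive over a partition of the universe", {
  sets <- list(a = paste0("g", 1:3), b = paste0("g", 4:7), c = paste0("g", 8:10))
  rates <- stats::setNames(rep(1e-5, 10), paste0("g", 1:10))
  ch <- simulate_dnm_cohort(sets, rates, 30000, seed = 11)
  parts <- vapply(sets, function(g) set_burden(ch, g)$observed, numeric(1))
  expect_equal(sum(parts), sum(ch$counts))
})

test_that("the relative-risk p-value equals the doubled conditional binomial tail", {
  rates <- stats::setNames(rep(1e-4, 4), c("a1", "a2", "b1", "b2"))
  mk <- function(oA, oB) {
    dnm_cohort("c", "autism", 12500,
               c(a1 = oA, a2 = 0L, b1 = oB, b2 = 0L), rates)
  }
  # symmetric case: RR 1, p 1
  res <- pairwise_relative_risk(mk(10L, 10L), c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$rr, 1)
  expect_equal(res$p_value, 1)
  # obs 10 vs 10 with expectations 5 vs 10: doubled tail of Binomial(20, 1/3)
  ch <- dnm_cohort("c", "autism", 1,
                   c(a1 = 10L, b1 = 10L), c(a1 = 2.5, b1 = 5))
  res2 <- pairwise_relative_risk(ch, "a1", "b1")
  expect_equal(res2$rr, 2)
  p_oracle <- 2 * min(pbinom(10, 20, 1/3), 1 - pbinom(9, 20, 1/3))
  expect_equal(res2$p_value, min(1, p_oracle), tolerance = 1e-12)
  # full enumeration oracle over all pairs with small totals
  for (oA in c(0L, 1L, 3L, 7L)) for (oB in c(0L, 2L, 5L)) {
    if (oA + oB == 0) next
    r <- pairwise_relative_risk(mk(oA, oB), c("a1", "a2"), c("b1", "b2"))
    n <- oA + oB; p0 <- 0.5
    pm <- dbinom(0:n, n, p0)
    lower <- sum(pm[seq_len(oA + 1)])
    upper <- sum(pm[(oA + 1):(n + 1)])
    expect_equal(r$p_value, min(1, 2 * min(lower, upper)), tolerance = 1e-12)
  }
})

test_that("relative risk inverts under swapping and CIs cover the point", {
  rates <- c(a1 = 2e-4, b1 = 1e-4)
  ch <- dnm_cohort("c", "DD", 5000, c(a1 = 9L, b1 = 2L), rates)
  ab <- pairwise_relative_risk(ch, "a1", "b1")
  ba <- pairwise_relative_risk(ch, "b1", "a1")
  expect_equal(ab$rr * ba$rr, 1)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(ab$rr_lo <= ab$rr && ab$rr <= ab$rr_hi)
  # degenerate: nothing observed
  ch0 <- dnm_cohort("c", "DD", 5000, c(a1 = 0L, b1 = 0L), rates)
  r0 <- pairwise_relative_risk(ch0, "a1", "b1")
  expect_equal(r0$p_value, 1)
  expect_true(is.na(r0$rr))
  # overlapping sets are rejected
  expect_error(pairwise_relative_risk(ch, c("a1", "b1"), "b1"), "config error")
})

test_that("null relative-risk p-values are super-uniform", {
  sets <- list(a = paste0("a", 1:20), b = paste0("b", 1:20))
  rates <- stats::setNames(rep(2e-5, 40), c(paste0("a", 1:20), paste0("b", 1:20)))
  ps <- vapply(1:400, function(i) {
    ch <- simulate_dnm_cohort(sets, rates, 20000, seed = 1000 + i)
    pairwise_relative_risk(ch, sets$a, sets$b)$p_value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the burden test Bonferroni-adjusts over set pairs", {
  sets <- list(a = paste0("a", 1:5), b = paste0("b", 1:5), c = paste0("c", 1:5))
  genes <- unlist(sets)
  rates <- stats::setNames(rep(1e-5, 15), genes)
  ch <- simulate_dnm_cohort(sets, rates, 40000,
                            enrichment = c(a = 5, b = 1, c = 1), seed = 6)
  bt <- dnm_burden_test(ch)
  expect_equal(nrow(bt$pairs), 3)
  expect_equal(bt$pairs$p_bonferroni,
               pmin(1, bt$pairs$p_value * 3))
  expect_equal(sort(bt$burden$gene_set), sort(names(sets)))
})

test_that("cohort tables round-trip through the exchange format", {
  df <- data.frame(gene = c("g1", "g2"), cohort_id = "coh", phenotype = "DD",
                   observed_count = c(2L, 0L), mutation_rate = c(1e-5, 2e-5),
                   n_probands = 31052L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, path)
  ch <- read_dnm_cohort(path)
  expect_s3_class(ch, "DnmCohort")
  expect_equal(ch$n_probands, 31052L)
  expect_equal(unname(ch$counts["g1"]), 2L)
  expect_equal(unname(ch$rates["g2"]), 2e-5)
})
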