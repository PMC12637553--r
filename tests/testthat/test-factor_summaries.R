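# Builds a FactorModel directly from explicit parameter matrices, bypassing
# training, so summary arithmetic can be checked in closed form.
manual_model <- function(W, H, l, S, cells, gene_symbols = NULL) {
  batch_levels <- sort(unique(cells$batch_id))
  structure(list(
    W = W, H = H, l = l, S = S, a = rep(2, ncol(H)),
    batch_levels = batch_levels,
    batch_index = match(cells$batch_id, batch_levels),
    cell_ids = cells$cell_id,
    gene_symbols = if (is.null(gene_symbols)) paste0("G", seq_len(ncol(H)))
                   else gene_symbols,
    active_mask = NULL, config = training_config()),
    class = "FactorModel")
}

test_that("regional proportions reproduce hand arithmetic", {
  # 2 cells in one region: factor-1 contributions 90 and 98 summed over
  # genes, background 10 and 2 -> factor share 94/100
  cells <- toy_cells(2, region = "thalamus")
  W <- matrix(c(90, 98), 2, 1)
  H <- matrix(c(0.5, 0.5), 1, 2)
  S <- matrix(c(5, 1), 1, 2)
  m <- manual_model(W, H, l = c(1, 1), S = S, cells)
  data <- ExpressionMatrix(matrix(0L, 2, 2), cells, toy_panel(2))
  rs <- region_factor_summary(m, data)
  expect_equal(unname(rs$mean_counts["thalamus", "factor1"]), 94)
  expect_equal(unname(rs$mean_counts["thalamus", "background"]), 6)
  expect_equal(unname(rs$proportions["thalamus", "factor1"]), 0.94)
  expect_equal(sum(rs$proportions["thalamus", ]), 1)
})

test_that("single factor with no background captures the whole proportion", {
  cells <- toy_cells(3, region = "gz")
  m <- manual_model(matrix(1, 3, 1), matrix(c(2, 3), 1, 2), rep(1, 3),
                    matrix(0, 1, 2), cells)
  data <- ExpressionMatrix(matrix(0L, 3, 2), cells, toy_panel(2))
  rs <- region_factor_summary(m, data)
  expect_equal(unname(rs$proportions["gz", "factor1"]), 1)
})

test_that("regional summaries are invariant to cell order", {
  sim <- small_sim()
  tr <- sim$truth
  cells <- sim$data$cells
  m <- manual_model(tr$W, tr$H, tr$l, tr$S, cells,
                    gene_symbols = sim$data$genes$gene_symbol)
  rs1 <- region_factor_summary(m, sim$data)
  perm <- sample(nrow(cells))
  m2 <- manual_model(tr$W[perm, ], tr$H, tr$l[perm], tr$S, cells[perm, ],
                     gene_symbols = sim$data$genes$gene_symbol)
  rs2 <- region_factor_summary(m2, sim$data[perm, ])
  expect_equal(rs1$mean_counts, rs2$mean_counts, tolerance = 1e-12)
  expect_equal(rs1$observed_mean_counts, rs2$observed_mean_counts)
})

test_that("relative loadings solve the two-region closed form", {
  # region A cells load factor 1 only, region B factor 2 only; gene 1 is
  # produced by factor 1 alone -> relative loading (1, 0)
  cells <- toy_cells(4, region = c("A", "A", "B", "B"))
  W <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  H <- rbind(c(2, 1), c(0, 3))
  m <- manual_model(W, H, rep(1, 4), matrix(0, 1, 2), cells)
  data <- ExpressionMatrix(matrix(0L, 4, 2), cells, toy_panel(2))
  lt <- relative_gene_loading(m, data)
  expect_equal(unname(lt$loadings["G1", ]), c(1, 0))
  expect_true(lt$enriched["G1", 1] && !lt$enriched["G1", 2])
  expect_equal(rowSums(lt$loadings) + lt$background_share, c(1, 1),
               ignore_attr = TRUE)
  # background-only gene: H column zero but ambient present
  H2 <- rbind(c(2, 0), c(0, 0))
  m2 <- manual_model(W, H2, rep(1, 4), matrix(c(0, 0.4), 1, 2), cells)
  lt2 <- relative_gene_loading(m2, data)
  expect_equal(unname(lt2$background_share["G2"]), 1)
  expect_equal(unname(lt2$loadings["G2", ]), c(0, 0))
})

test_that("vectorized relative loadings equal a brute-force oracle", {
  cfg <- simulation_config(n_cells_per_region = 10,
                           regions = c("A", "B", "C", "D", "E"),
                           n_factors_true = 3, n_genes = 12, n_batches = 2,
                           seed = 77)
  sim <- simulate_dataset(cfg)   # 50 cells
  tr <- sim$truth
  m <- manual_model(tr$W, tr$H, tr$l, tr$S, sim$data$cells,
                    gene_symbols = sim$data$genes$gene_symbol)
  lt <- relative_gene_loading(m, sim$data)
  # oracle: loop cells and factors through reconstruct_mean
  regions <- sort(unique(sim$data$cells$region_label))
  Fn <- ncol(tr$W); G <- ncol(tr$H)
  per_factor <- array(0, c(length(regions), Fn, G))
  bg <- matrix(0, length(regions), G)
  for (ri in seq_along(regions)) {
    sel <- which(sim$data$cells$region_label == regions[ri])
    for (f in seq_len(Fn)) {
      per_factor[ri, f, ] <- colMeans(reconstruct_mean(m, cells = sel,
                                                       factor = f))
    }
    bg[ri, ] <- colMeans(reconstruct_mean(m, cells = sel,
                                          factor = "background"))
  }
  fac_avg <- apply(per_factor, c(2, 3), mean)   # factors x genes
  bg_avg <- colMeans(bg)
  denom <- colSums(fac_avg) + bg_avg
  oracle <- t(fac_avg) / denom
  expect_equal(unname(lt$loadings), unname(oracle), tolerance = 1e-10)
  expect_equal(unname(lt$background_share), unname(bg_avg / denom),
               tolerance = 1e-10)
})

test_that("the robust threshold is the median of per-gene regional maxima", {
  # 10 cells in one region; counts chosen so the per-gene regional means are
  # exactly 0.1, 0.5, 0.6 and 2.0 -> even-count median 0.55
  cells1 <- toy_cells(10, region = "A")
  counts1 <- matrix(0L, 10, 4)
  counts1[1, 1] <- 1L                 # gene1 mean 0.1
  counts1[1:5, 2] <- 1L               # gene2 mean 0.5
  counts1[1:6, 3] <- 1L               # gene3 mean 0.6
  counts1[, 4] <- 2L                  # gene4 mean 2.0
  d1 <- ExpressionMatrix(counts1, cells1, toy_panel(4))
  thr <- robust_expression_threshold(d1, regions = "A")
  expect_equal(as.numeric(thr), 0.55)
  expect_equal(unname(attr(thr, "max_regional_mean")), c(0.1, 0.5, 0.6, 2.0))
  # identical genes: threshold equals the common value
  d_same <- ExpressionMatrix(matrix(1L, 10, 4), cells1, toy_panel(4))
  expect_equal(as.numeric(robust_expression_threshold(d_same, "A")), 1)
  # invariant to cell order and region order
  sim <- small_sim()
  regs <- unique(sim$data$cells$region_label)
  t1 <- robust_expression_threshold(sim$data, regs)
  t2 <- robust_expression_threshold(sim$data, rev(regs))
  perm <- sample(nrow(sim$data$counts))
  t3 <- robust_expression_threshold(sim$data[perm, ], regs)
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_equal(as.numeric(t1), as.numeric(t3))
  expect_error(robust_expression_threshold(d1, character(0)), "config error")
})

test_that("overlapping genes go to the factor with the higher loading", {
  lt <- structure(list(
    loadings = rbind(G1 = c(0.4, 0.4, 0.2),
                     G2 = c(0.5, 0.34, 0.16),
                     G3 = c(0.6, 0.2, 0.2),
                     G4 = c(0.2, 0.3, 0.5)),
    background_share = rep(0, 4),
    max_regional_mean = rep(1, 4),
    enriched = rbind(c(TRUE, TRUE, FALSE),
                     c(TRUE, TRUE, FALSE),
                     c(TRUE, FALSE, FALSE),
                     c(FALSE, FALSE, TRUE)),
    robust = rep(TRUE, 4),
    assigned_factor = rep(NA_integer_, 4),
    enrichment_threshold = 0.33, robust_threshold = 0.5),
    class = "GeneLoadingTable")
  colnames(lt$loadings) <- paste0("factor", 1:3)
  expect_warning(out <- assign_overlapping_genes(lt), "tied")
  expect_equal(out$assigned_factor, c(1L, 1L, 1L, 3L))
  sets <- factor_gene_sets(out)
  expect_equal(sort(sets$factor1), c("G1", "G2", "G3"))
  expect_equal(sets$factor3, "G4")
})

test_that("raising the enrichment threshold never adds enriched genes", {
  sim <- small_sim()
  tr <- sim$truth
  m <- manual_model(tr$W, tr$H, tr$l, tr$S, sim$data$cells,
                    gene_symbols = sim$data$genes$gene_symbol)
  n_enriched <- vapply(c(0.1, 0.2, 0.33, 0.5, 0.7), function(thr) {
    lt <- relative_gene_loading(m, sim$data, enrichment_threshold = thr)
    sum(lt$enriched)
  }, numeric(1))
  expect_true(all(diff(n_enriched) <= 0))
})

test_that("category tests match Fisher's exact hypergeometric enumeration", {
  # balanced table -> OR 1, p 1
  panel <- toy_panel(40)
  panel$categories <- rep(c("axons", ""), each = 20)
  res <- suppressWarnings(category_enrichment(paste0("G", c(1:10, 21:30)), panel))
  axons <- res[res$category == "axons", ]
  expect_equal(axons$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(axons$p_value, 1, tolerance = 1e-12)
  # 8/2 vs 2/8 against direct enumeration of tables with fixed margins
  panel2 <- toy_panel(20)
  panel2$categories <- rep(c("cell cycle", ""), each = 10)
  infac <- paste0("G", c(1:8, 11:12))   # 8 in category, 2 out
  res2 <- suppressWarnings(category_enrichment(infac, panel2))
  cc <- res2[res2$category == "cell cycle", ]
  p_enum <- sum(vapply(0:10, function(a) {
    p <- dhyper(a, 10, 10, 10)
    if (p <= dhyper(8, 10, 10, 10) + 1e-12) p else 0
  }, numeric(1)))
  expect_equal(cc$p_value, p_enum, tolerance = 1e-10)
  # absent category -> NA with warning
  w <- testthat::capture_warnings(
    res3 <- category_enrichment("G1", toy_panel(5)))
  expect_true(all(grepl("absent", w)) && length(w) > 0)
  expect_true(all(is.na(res3$p_value)))
})
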