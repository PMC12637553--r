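test_that("the NB log-likelihood matches its limits and normalizes", {
  # Poisson limit
  expect_equal(nb_log_likelihood(0, 2, 1e8), -2, tolerance = 1e-4)
  expect_equal(nb_log_likelihood(3, 2.5, 1e9),
               dpois(3, 2.5, log = TRUE), tolerance = 1e-4)
  # normalization by direct summation
  total <- sum(exp(nb_log_likelihood(0:2000, rep(3, 2001), rep(2, 2001))))
  expect_equal(total, 1, tolerance = 1e-8)
  # increasing alpha moves the implied variance toward the mean
  alphas <- c(0.5, 1, 2, 10, 100)
  vars <- 3 + 9 / alphas
  expect_true(all(diff(vars) < 0))
  expect_error(nb_log_likelihood(1, -1, 2), "numeric error")
  expect_error(nb_log_likelihood(1, Inf, 2), "numeric error")
})

test_that("per-factor contributions and background sum to the full mean", {
  sim <- small_sim()
  tr <- sim$truth
  m <- structure(list(W = tr$W, H = tr$H, l = tr$l, S = tr$S, a = tr$a,
                      batch_levels = sort(unique(sim$data$cells$batch_id)),
                      batch_index = tr$batch_index,
                      cell_ids = sim$data$cells$cell_id,
                      gene_symbols = sim$data$genes$gene_symbol,
                      active_mask = NULL, config = training_config()),
                 class = "FactorModel")
  full <- reconstruct_mean(m)
  acc <- reconstruct_mean(m, factor = "background")
  for (f in seq_len(ncol(m$W))) acc <- acc + reconstruct_mean(m, factor = f)
  expect_equal(acc, full, tolerance = 1e-10)
  # a zero cell-loading column contributes nothing
  m0 <- m; m0$W[, 2] <- 0
  expect_equal(reconstruct_mean(m0, factor = 2),
               matrix(0, nrow(m$W), ncol(m$H)), ignore_attr = TRUE)
  expect_error(reconstruct_mean(m, factor = 99), "index error")
})

test_that("activity scores split into clusters as specified", {
  # separated clusters
  expect_equal(spanmf:::split_scores_2means(c(10, 10, 10, 0.01, 0.01)),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # identical scores: warning, all retained
  expect_warning(mask <- spanmf:::split_scores_2means(rep(2, 6)),
                 "indistinguishable|not separated")
  expect_true(all(mask))
  # numerically dead factors are inactive even when the rest are uniform
  mask2 <- spanmf:::split_scores_2means(c(2, 2, 2, 1e-9))
  expect_equal(mask2, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("training recovers a small planted factor structure", {
  cfg <- simulation_config(n_cells_per_region = 300,
                           regions = c("thalamus", "germinal zones",
                                       "cortical plate"),
                           n_factors_true = 3, n_genes = 50, n_batches = 2,
                           seed = 15)
  sim <- simulate_dataset(cfg)
  m <- nmf_fit(sim$data, genes = seq_len(50),
               config = training_config(n_factors_init = 6, epochs = 2500,
                                        learning_rate = 0.01, seed = 2))
  # invariants: positivity and per-section mean efficiency 1
  expect_true(all(m$W >= 0) && all(m$H >= 0) && all(m$S >= 0))
  expect_true(all(m$l > 0) && all(m$a > 0))
  for (e in seq_along(m$batch_levels)) {
    expect_equal(mean(m$l[m$batch_index == e]), 1, tolerance = 1e-6)
  }
  # loss improves
  expect_gt(utils::tail(m$training_log$loglik, 1),
            utils::head(m$training_log$loglik, 1))
  mask <- suppressWarnings(select_active_factors(m))
  mp <- prune_factors(m, mask)
  expect_gte(sum(mask), 3)
  mt <- match_factors(mp$H, sim$truth$H)
  expect_gte(mt$mean_cosine, 0.85)
})

test_that("a zero-count gene is driven to negligible loadings", {
  cfg <- simulation_config(n_cells_per_region = 200, regions = c("A", "B"),
                           n_factors_true = 2, n_genes = 20, n_batches = 1,
                           seed = 19)
  sim <- simulate_dataset(cfg)
  data <- sim$data
  counts <- as.matrix(data$counts)
  counts[, 7] <- 0L
  data2 <- ExpressionMatrix(counts, data$cells, data$genes)
  m <- nmf_fit(data2, genes = seq_len(20),
               config = training_config(n_factors_init = 4, epochs = 1500,
                                        learning_rate = 0.01, seed = 2))
  expect_lt(max(m$H[, 7]), 1e-3 * mean(m$H))
  expect_lt(max(m$S[, 7]), 1e-3 * mean(m$S) + 1e-6)
})

test_that("factor matching maximizes assignment similarity", {
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1))
  perm <- c(3, 1, 2)
  mt <- match_factors(H[perm, ], H)
  expect_equal(mt$assignment, perm)
  expect_equal(mt$mean_cosine, 1, tolerance = 1e-12)
  # fewer estimated than reference rows
  mt2 <- match_factors(H[1:2, ], H)
  expect_equal(mt2$assignment, 1:2)
})

test_that("a saved model reloads identically", {
  sim <- small_sim()
  m <- nmf_fit(sim$data, genes = seq_len(30),
               config = training_config(n_factors_init = 4, epochs = 200,
                                        learning_rate = 0.01, seed = 5))
  dir <- withr::local_tempdir()
  write_factor_model(m, dir)
  back <- read_factor_model(dir)
  expect_equal(back$W, m$W, tolerance = 1e-12)
  expect_equal(back$H, m$H, tolerance = 1e-12)
  expect_equal(back$l, m$l, tolerance = 1e-12)
  expect_equal(back$S, m$S, tolerance = 1e-12)
  expect_equal(back$a, m$a, tolerance = 1e-12)
  expect_identical(back$batch_index, m$batch_index)
  expect_identical(back$cell_ids, m$cell_ids)
})
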