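#' Negative Binomial log-likelihood (mean/concentration form)
#'
#' Log-pmf of the NB distribution parameterized by mean `mu` and
#' concentration `alpha`, so that the variance is `mu + mu^2/alpha`
#' (Poisson limit as `alpha -> Inf`).
#'
#' @param x non-negative integer count(s).
#' @param mu positive mean(s).
#' @param alpha positive concentration(s).
#' @return log-probability, vectorized over the inputs.
#' @export
nb_log_likelihood <- function(x, mu, alpha) {
  if (any(!is.finite(x)) || any(!is.finite(mu)) || any(!is.finite(alpha))) {
    stop("numeric error: non-finite input to nb_log_likelihood", call. = FALSE)
  }
  if (any(mu <= 0) || any(alpha <= 0) || any(x < 0) || any(x != floor(x))) {
    stop("numeric error: require mu > 0, alpha > 0, integer x >= 0",
         call. = FALSE)
  }
  stats::dnbinom(x, size = alpha, mu = mu, log = TRUE)
}

# Shared mean function of the generative/inference model:
#   mu_cg = l_c * (S_{e(c),g} + sum_f W_cf H_fg).
# Both the simulator and reconstruct_mean() go through here.
nmf_mean_matrix <- function(W, H, l, S, batch_index) {
  M <- S[batch_index, , drop = FALSE] + W %*% H
  M * l
}

#' Training configuration for the probabilistic factorization
#'
#' Defaults are sized for desk-scale data: the reference protocol for the
#' full 10.86M-cell atlas (10 initial factors, 40,000 epochs, learning rate
#' 0.001, multi-million-cell batches) is scaled down to full-batch training
#' with fewer epochs and a correspondingly larger step size.
#'
#' @param n_factors_init number of factors at initialization (default 10).
#' @param epochs optimization steps (default 4000).
#' @param learning_rate Adam step size (default 0.005).
#' @param minibatch_size cells per stochastic minibatch; `Inf` (default)
#'   trains full-batch. Datasets smaller than the minibatch fall back to
#'   full-batch automatically.
#' @param seed integer RNG seed, recorded in the model.
#' @param quantile_for_activity quantile of loadings used by
#'   [select_active_factors()] (default 0.999).
#' @param prior_shape_w,prior_rate_w Gamma prior on cell loadings; a shape
#'   below 1 favours concentrating a cell's loading on few factors, which is
#'   what lets redundant factors decay to zero.
#' @param prior_shape_h,prior_rate_h Gamma prior on gene loadings.
#' @param prior_rate_s exponential prior rate on ambient background.
#' @param prior_sd_logl,prior_sd_loga log-normal prior SDs on detection
#'   efficiency and NB concentration. The efficiency default (0.3) reflects
#'   the typical spread of per-cell capture efficiency in imaging-based
#'   panels and doubles as the lever that keeps per-cell scale from leaking
#'   between `l` and `W`.
#' @param ard automatic relevance determination: per-factor exponential
#'   rates on `W` re-estimated from the fitted loadings during training, so
#'   that factors the data do not support collapse to zero.
#' @param cell_total_prior hierarchical Gamma prior on each cell's total
#'   loading, hyperparameters fitted by moment matching during training;
#'   this pins the attribution of per-cell scale between `W` and `l`.
#' @param warmup_frac fraction of epochs before the hierarchical priors
#'   switch on (hyperparameters are meaningless while the fit is far from
#'   the data).
#' @param hyper_update_every epochs between hyperparameter refreshes.
#' @param init_stagger geometric ratio of initial factor scales; values
#'   below 1 stagger the factors so they claim structure sequentially
#'   rather than splitting it symmetrically.
#' @param min_factor_support minimum fraction of cells that must carry a
#'   meaningful loading (a tenth of the factor's extreme loading) for a
#'   factor to stay alive (default 1%); "ghost" factors below this support
#'   are culled during training. Co-expression programs of interest are
#'   tissue-scale; fitted ghosts sit orders of magnitude below real
#'   programs (tenths of a percent versus tens of percent of cells). Lower
#'   the threshold when genuinely rare regional programs are expected; set
#'   to 0 to disable.
#' @param merge_threshold cosine similarity of gene-loading rows above which
#'   two live factors are treated as one co-expression program and merged
#'   (their cell loadings add; the emptied factor decays). Merging is exact
#'   when the rows are collinear, since the likelihood depends only on the
#'   summed contribution. Set above 1 to disable.
#' @return a `TrainingConfig` list.
#' @export
training_config <- function(n_factors_init = 10, epochs = 4000,
                            learning_rate = 0.005, minibatch_size = Inf,
                            seed = 1, quantile_for_activity = 0.999,
                            prior_shape_w = 0.3, prior_rate_w = 1,
                            prior_shape_h = 0.3, prior_rate_h = 1,
                            prior_rate_s = 5, prior_sd_logl = 0.3,
                            prior_sd_loga = 2, ard = TRUE,
                            cell_total_prior = TRUE, warmup_frac = 0.2,
                            hyper_update_every = 25, init_stagger = 1,
                            merge_threshold = 0.8,
                            min_factor_support = 0.01) {
  stopifnot(n_factors_init >= 1, epochs >= 1, learning_rate > 0,
            minibatch_size > 0,
            quantile_for_activity > 0, quantile_for_activity < 1,
            warmup_frac >= 0, warmup_frac < 1)
  structure(list(n_factors_init = as.integer(n_factors_init),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 minibatch_size = minibatch_size, seed = as.integer(seed),
                 quantile_for_activity = quantile_for_activity,
                 prior_shape_w = prior_shape_w, prior_rate_w = prior_rate_w,
                 prior_shape_h = prior_shape_h, prior_rate_h = prior_rate_h,
                 prior_rate_s = prior_rate_s, prior_sd_logl = prior_sd_logl,
                 prior_sd_loga = prior_sd_loga, ard = ard,
                 cell_total_prior = cell_total_prior,
                 warmup_frac = warmup_frac,
                 hyper_update_every = as.integer(hyper_update_every),
                 init_stagger = init_stagger,
                 merge_threshold = merge_threshold,
                 min_factor_support = min_factor_support),
            class = "TrainingConfig")
}

softplus <- function(u) log1p(exp(-abs(u))) + pmax(u, 0)
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

#' Fit the technical-variation-aware NB factorization
#'
#' Decomposes raw counts into non-negative cell loadings `W` and gene
#' loadings `H`, with per-cell detection efficiency `l_c`, per-section x gene
#' ambient background `S_eg` and per-gene NB concentration `a_g`:
#' `X_cg ~ NB(mean = l_c (S_eg + sum_f W_cf H_fg), concentration = a_g)`.
#' Parameters are MAP estimates obtained by (optionally stochastic) Adam
#' ascent on the log posterior, with softplus/log parameterizations keeping
#' every parameter positive throughout. After training, `l` is rescaled to
#' mean 1 within each section (`W` and `S` absorb the scale), fixing the
#' multiplicative indeterminacy.
#'
#' @param data ExpressionMatrix, already QC-filtered.
#' @param genes genes to factorize: logical/integer/character selector;
#'   default is the panel's susceptibility genes excluding cell-type markers.
#' @param config a [training_config()].
#' @param verbose print progress every 500 epochs.
#' @return a `FactorModel`: `W`, `H`, `l`, `S`, `a`, `batch_levels`,
#'   `batch_index`, `cell_ids`, `gene_symbols`, `active_mask` (NULL until
#'   [select_active_factors()]), `training_log`, `config`, `seed`.
#' @export
nmf_fit <- function(data, genes = NULL, config = training_config(),
                    verbose = FALSE) {
  stopifnot(inherits(data, "ExpressionMatrix"),
            inherits(config, "TrainingConfig"))
  if (is.null(genes)) genes <- data$genes$is_susceptibility & !data$genes$is_marker
  sub <- data[, genes]
  X <- as.matrix(sub$counts)
  n <- nrow(X); G <- ncol(X); Fi <- config$n_factors_init
  batch_levels <- sort(unique(sub$cells$batch_id))
  batch_index <- match(sub$cells$batch_id, batch_levels)
  E <- length(batch_levels)

  set.seed(config$seed)
  gm <- pmax(colMeans(X), 1e-3)
  # H: gene-wise mean split across factors by Dirichlet noise; W ~ mean 0.5.
  # Factor scales are staggered geometrically so factors enter the fit in a
  # pecking order: early factors claim co-expression structure first and
  # surplus factors, finding only residue, decay instead of splitting a
  # claimed factor symmetrically.
  D <- matrix(stats::rgamma(Fi * G, shape = 1), Fi, G)
  D <- sweep(D, 2, colSums(D), "/")
  stag <- config$init_stagger^(seq_len(Fi) - 1L)
  uH <- inv_softplus(sweep(D, 2, 2 * gm, "*") * stag + 1e-4)
  uW <- inv_softplus(matrix(stats::rgamma(n * Fi, shape = 2, rate = 4), n, Fi) + 1e-4)
  uS <- matrix(inv_softplus(0.01), E, G)
  ul <- rep(0, n)
  ua <- rep(log(1), G)

  mb <- config$minibatch_size
  full_batch <- !is.finite(mb) || mb >= n
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  adam <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0)
  st <- list(W = adam(c(n, Fi)), H = adam(c(Fi, G)), S = adam(c(E, G)),
             l = adam(n), a = adam(G))
  step <- function(s, g, idx = NULL) {
    s$t <- s$t + 1
    ct <- lr * sqrt(1 - b2^s$t) / (1 - b1^s$t)
    if (is.null(idx)) {
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      delta <- ct * s$m / (sqrt(s$v) + eps)
    } else {
      s$m[idx, ] <- b1 * s$m[idx, , drop = FALSE] + (1 - b1) * g
      s$v[idx, ] <- b2 * s$v[idx, , drop = FALSE] + (1 - b2) * g^2
      delta <- ct * s$m[idx, , drop = FALSE] / (sqrt(s$v[idx, , drop = FALSE]) + eps)
    }
    list(s = s, delta = delta)
  }

  log_every <- max(1L, config$epochs %/% 200L)
  log_epochs <- integer(0); log_ll <- numeric(0)
  warmup <- ceiling(config$warmup_frac * config$epochs)
  rate_w <- rep(config$prior_rate_w, Fi)   # per-factor (ARD) rates
  k0 <- NA_real_; r0 <- NA_real_           # cell-total Gamma hyperparameters
  for (it in seq_len(config$epochs)) {
    if (full_batch) {
      idx <- seq_len(n); scale <- 1
    } else {
      idx <- sample.int(n, mb); scale <- n / mb
    }
    W <- softplus(uW[idx, , drop = FALSE]); H <- softplus(uH)
    S <- softplus(uS); l <- exp(ul[idx]); a <- exp(ua)
    if (it > warmup && (it - warmup == 1L ||
                        it %% config$hyper_update_every == 0L)) {
      Wfull <- if (full_batch) W else softplus(uW)
      if (config$ard) rate_w <- 1 / (colMeans(Wfull) + 0.01)
      if (config$min_factor_support > 0) {
        qf <- apply(Wfull, 2, stats::quantile, probs = 0.999, names = FALSE)
        thr <- 0.1 * pmax(qf, 1e-12)
        support <- vapply(seq_along(thr),
                          function(f) mean(Wfull[, f] > thr[f]), numeric(1))
        ghost <- which(qf > 1e-6 & support < config$min_factor_support)
        for (f in ghost) {
          uW[, f] <- -30
          st$W$m[, f] <- 0; st$W$v[, f] <- 0
          Wfull[, f] <- softplus(-30)
        }
      }
      if (config$merge_threshold <= 1) {
        H_now <- softplus(uH)
        cm <- colMeans(Wfull)
        alive <- which(cm > 1e-3 * max(cm))
        if (length(alive) >= 2) {
          Rn <- H_now[alive, , drop = FALSE] / pmax(rowSums(H_now[alive, , drop = FALSE]), 1e-12)
          Rn <- Rn / sqrt(rowSums(Rn^2) + 1e-300)
          Cs <- Rn %*% t(Rn)
          for (ii in seq_along(alive)) for (jj in seq_len(ii - 1L)) {
            if (Cs[ii, jj] >= config$merge_threshold) {
              keep <- alive[ii]; kill <- alive[jj]
              if (cm[kill] > cm[keep]) { tmp <- keep; keep <- kill; kill <- tmp }
              uW[, keep] <- inv_softplus(softplus(uW[, keep]) +
                                           softplus(uW[, kill]))
              uW[, kill] <- -20
              uH[kill, ] <- -20
              st$W$m[, c(keep, kill)] <- 0; st$W$v[, c(keep, kill)] <- 0
              st$H$m[c(keep, kill), ] <- 0; st$H$v[c(keep, kill), ] <- 0
              cm[kill] <- 0
            }
          }
        }
      }
      if (config$cell_total_prior) {
        tot <- rowSums(Wfull)
        k0 <- min(20, max(1, mean(tot)^2 / stats::var(tot)))
        r0 <- 1 / (mean(tot) + 0.01)   # self-neutralizing at the mean
      }
    }
    want_a <- (it %% 5L == 0L) || it > config$epochs - 20L
    want_ll <- (it %% log_every == 0L) || it == config$epochs
    Xb <- if (full_batch) X else X[idx, , drop = FALSE]
    res <- nmf_step_cpp(Xb, W, H, S, l, a, batch_index[idx] - 1L,
                        want_ll, want_a)
    if (any(!is.finite(res$gl)) || (want_ll && !is.finite(res$ll))) {
      stop("training error: divergent loss at epoch ", it,
           "; try a smaller learning rate", call. = FALSE)
    }
    gW <- res$gW + (config$prior_shape_w - 1) / (W + 1e-8)
    gW <- sweep(gW, 2, rate_w, "-")
    if (!is.na(k0)) {
      # shape-only pull of each cell's total loading toward the population
      # mean; deliberately scale-neutral (no net shrink or growth)
      rs <- rowSums(W)
      gW <- gW + (k0 - 1) * (1 / (rs + 0.01) - r0)   # recycles per cell row
    }
    gW <- gW * stats::plogis(uW[idx, , drop = FALSE])
    gH <- (scale * res$gH + (config$prior_shape_h - 1) / (H + 1e-8) -
             config$prior_rate_h) * stats::plogis(uH)
    gS <- (scale * res$gS - config$prior_rate_s) * stats::plogis(uS)
    gl <- as.numeric(res$gl) * l - ul[idx] / config$prior_sd_logl^2
    upd <- step(st$W, gW, idx); st$W <- upd$s
    uW[idx, ] <- uW[idx, , drop = FALSE] + upd$delta
    upd <- step(st$H, gH); st$H <- upd$s; uH <- uH + upd$delta
    upd <- step(st$S, gS); st$S <- upd$s; uS <- uS + upd$delta
    dl <- numeric(n); dl[idx] <- gl
    upd <- step(st$l, dl); st$l <- upd$s; ul <- as.numeric(ul + upd$delta)
    if (want_a) {
      ga <- scale * as.numeric(res$galpha) * a - ua / config$prior_sd_loga^2
      upd <- step(st$a, ga); st$a <- upd$s; ua <- as.numeric(ua + upd$delta)
    }
    if (want_ll) {
      log_epochs <- c(log_epochs, it)
      log_ll <- c(log_ll, scale * res$ll)
      if (verbose && it %% 500L == 0L) {
        message("epoch ", it, " loglik ", format(scale * res$ll))
      }
    }
  }
  training_log <- data.frame(epoch = log_epochs, loglik = log_ll)

  W <- softplus(uW); H <- softplus(uH); S <- softplus(uS)
  l <- exp(ul); a <- exp(ua)
  stopifnot(all(W >= 0), all(H >= 0), all(S >= 0), all(l > 0), all(a > 0))
  # fix the scale indeterminacy: mean detection efficiency 1 per section
  for (e in seq_len(E)) {
    sel <- batch_index == e
    k <- mean(l[sel])
    l[sel] <- l[sel] / k
    W[sel, ] <- W[sel, ] * k
    S[e, ] <- S[e, ] * k
  }
  structure(list(W = W, H = H, l = l, S = S, a = a,
                 batch_levels = batch_levels, batch_index = batch_index,
                 cell_ids = sub$cells$cell_id,
                 gene_symbols = sub$genes$gene_symbol,
                 active_mask = NULL, training_log = training_log,
                 config = config, seed = config$seed),
            class = "FactorModel")
}

#' @export
print.FactorModel <- function(x, ...) {
  cat("FactorModel:", nrow(x$W), "cells x", ncol(x$W), "factors x",
      ncol(x$H), "genes,", length(x$batch_levels), "sections\n")
  if (!is.null(x$active_mask)) {
    cat("  active factors:", sum(x$active_mask), "of", length(x$active_mask), "\n")
  }
  invisible(x)
}

#' Split factors into active and inactive by their extreme loadings
#'
#' For each factor, the `quantile_for_activity` (default 99.9%) quantile is
#' taken over its cell loadings and over its gene loadings; the two are
#' combined by geometric mean into one activity score. Scores are split on
#' the log scale by exact 1-D 2-means; the high cluster is active. If the
#' two clusters are separated by less than `gap_tol` on the log scale the
#' split is considered unreliable and all factors are retained with a
#' warning.
#'
#' @param model FactorModel
#' @param quantile_for_activity quantile of loadings (default from the
#'   model's training config).
#' @param gap_tol minimum log-scale separation of cluster means
#'   (default `log(2)`).
#' @return logical vector over factors, `TRUE` = active, with the activity
#'   scores in `attr(, "scores")`.
#' @export
select_active_factors <- function(model,
                                  quantile_for_activity = model$config$quantile_for_activity,
                                  gap_tol = log(2)) {
  stopifnot(inherits(model, "FactorModel"))
  q <- quantile_for_activity
  qc <- apply(model$W, 2, stats::quantile, probs = q, names = FALSE)
  qg <- apply(model$H, 1, stats::quantile, probs = q, names = FALSE)
  scores <- sqrt(qc * qg)
  mask <- split_scores_2means(scores, gap_tol)
  attr(mask, "scores") <- scores
  mask
}

# Exact 1-D 2-means on log scores: try every ordered split, keep the one
# with minimal within-cluster sum of squares. Factors whose score has
# collapsed below 1e-3 of the top factor are inactive outright and excluded
# from the clustering, so numerically dead factors cannot masquerade as the
# "low cluster" and hide a real active/inactive split.
split_scores_2means <- function(scores, gap_tol = log(2)) {
  Fn <- length(scores)
  dead <- scores < 1e-3 * max(scores)
  live <- which(!dead)
  ls <- log(pmax(scores[live], 1e-300))
  if (length(live) < 2 || diff(range(ls)) < 1e-12) {
    if (!any(dead)) {
      warning("activity scores are indistinguishable; retaining all factors")
      return(rep(TRUE, Fn))
    }
    return(!dead)
  }
  o <- order(ls)
  s <- ls[o]
  k_n <- length(s)
  wss <- vapply(seq_len(k_n - 1), function(k) {
    lo <- s[1:k]; hi <- s[(k + 1):k_n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(wss)
  lo <- s[1:k]; hi <- s[(k + 1):k_n]
  if (mean(hi) - mean(lo) < gap_tol) {
    if (!any(dead)) {
      warning("active/inactive clusters are not separated; retaining all factors")
      return(rep(TRUE, Fn))
    }
    return(!dead)
  }
  mask <- rep(FALSE, Fn)
  mask[live[o[(k + 1):k_n]]] <- TRUE
  mask
}

#' Drop inactive factors from a fitted model
#'
#' @param model FactorModel
#' @param mask logical over factors (from [select_active_factors()]).
#' @return FactorModel with `W` columns / `H` rows restricted to active
#'   factors and `active_mask` recording the original positions.
#' @export
prune_factors <- function(model, mask) {
  stopifnot(inherits(model, "FactorModel"), length(mask) == ncol(model$W))
  model$W <- model$W[, mask, drop = FALSE]
  model$H <- model$H[mask, , drop = FALSE]
  model$active_mask <- mask
  model
}

#' Reconstructed model mean, in full or per factor
#'
#' @param model FactorModel
#' @param cells optional cell subset (indices or cell ids).
#' @param factor `NULL` for the full mean
#'   `mu = l (S + W H)`; an integer `f` for the single-factor contribution
#'   `l W_f H_f`; `"background"` for the ambient term `l S`.
#' @return dense matrix, cells x genes. Contributions over all factors plus
#'   the background term sum exactly to the full mean.
#' @export
reconstruct_mean <- function(model, cells = NULL, factor = NULL) {
  stopifnot(inherits(model, "FactorModel"))
  idx <- if (is.null(cells)) seq_along(model$l)
         else if (is.character(cells)) match(cells, model$cell_ids)
         else cells
  W <- model$W[idx, , drop = FALSE]
  l <- model$l[idx]
  bi <- model$batch_index[idx]
  if (is.null(factor)) {
    return(nmf_mean_matrix(W, model$H, l, model$S, bi))
  }
  if (identical(factor, "background")) {
    return(model$S[bi, , drop = FALSE] * l)
  }
  if (!(is.numeric(factor) && length(factor) == 1 && factor >= 1 &&
        factor <= ncol(W))) {
    stop("index error: unknown factor index ", factor, call. = FALSE)
  }
  (W[, factor, drop = FALSE] %*% model$H[factor, , drop = FALSE]) * l
}

#' Match estimated factors to reference factors
#'
#' Rows of both gene-loading matrices are normalized to unit sum (the scale
#' convention under which factors are comparable), cosine similarities are
#' computed for every pair, and the assignment maximizing total similarity
#' is found by exhaustive permutation search (factor counts here are small).
#'
#' @param H_est estimated gene-loading matrix (factors x genes).
#' @param H_ref reference gene-loading matrix (factors x genes).
#' @return list with `assignment` (for each estimated factor, the matched
#'   reference row), `cosines` (per matched pair) and `mean_cosine`.
#' @export
match_factors <- function(H_est, H_ref) {
  norm_rows <- function(M) {
    rs <- rowSums(M)
    M <- M / ifelse(rs > 0, rs, 1)
    M / sqrt(rowSums(M^2) + 1e-300)
  }
  A <- norm_rows(H_est); B <- norm_rows(H_ref)
  C <- A %*% t(B)
  ne <- nrow(A); nr <- nrow(B)
  k <- min(ne, nr)
  if (ne > 8 && nr > 8) {
    # greedy fallback for large factor counts
    assignment <- rep(NA_integer_, ne)
    Cw <- C
    for (i in seq_len(k)) {
      p <- arrayInd(which.max(Cw), dim(Cw))
      assignment[p[1]] <- p[2]
      Cw[p[1], ] <- -Inf; Cw[, p[2]] <- -Inf
    }
  } else if (ne <= nr) {
    perms <- all_permutations(nr, ne)
    tot <- apply(perms, 1, function(p) sum(C[cbind(seq_len(ne), p)]))
    assignment <- perms[which.max(tot), ]
  } else {
    perms <- all_permutations(ne, nr)
    tot <- apply(perms, 1, function(p) sum(C[cbind(p, seq_len(nr))]))
    best <- perms[which.max(tot), ]
    assignment <- rep(NA_integer_, ne)
    assignment[best] <- seq_len(nr)
  }
  matched <- !is.na(assignment)
  cosines <- C[cbind(which(matched), assignment[matched])]
  list(assignment = assignment, cosines = cosines,
       mean_cosine = mean(cosines))
}

# All ordered selections of k items from n (rows of a matrix).
all_permutations <- function(n, k = n) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(k - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], length(rest), j, byrow = TRUE), rest)
    }))
  }
  unname(out)
}

#' Save a fitted factor model as delimited matrices plus a YAML manifest
#' @param model FactorModel
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, f) utils::write.table(
    format(M, digits = 15, trim = TRUE), file.path(dir, f), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  wm(model$W, "W.tsv"); wm(model$H, "H.tsv"); wm(model$S, "S.tsv")
  wm(cbind(model$l), "l.tsv"); wm(cbind(model$a), "a.tsv")
  writeLines(model$cell_ids, file.path(dir, "cell_ids.txt"))
  writeLines(model$gene_symbols, file.path(dir, "gene_symbols.txt"))
  writeLines(model$batch_levels[model$batch_index], file.path(dir, "batch.txt"))
  write_table(model$training_log, file.path(dir, "training_log.tsv"))
  yaml::write_yaml(list(
    n_cells = nrow(model$W), n_factors = ncol(model$W),
    n_genes = ncol(model$H), batch_levels = as.list(model$batch_levels),
    active_mask = if (is.null(model$active_mask)) NULL else as.list(model$active_mask),
    seed = model$seed, config = unclass(model$config)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a factor model saved by [write_factor_model()]
#' @param dir model directory
#' @return FactorModel
#' @export
read_factor_model <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  batch <- readLines(file.path(dir, "batch.txt"))
  batch_levels <- unlist(man$batch_levels)
  cfg <- do.call(training_config, man$config[names(man$config) %in%
                                             names(formals(training_config))])
  structure(list(
    W = unname(rm_("W.tsv")), H = unname(rm_("H.tsv")), S = unname(rm_("S.tsv")),
    l = as.numeric(rm_("l.tsv")), a = as.numeric(rm_("a.tsv")),
    batch_levels = batch_levels, batch_index = match(batch, batch_levels),
    cell_ids = readLines(file.path(dir, "cell_ids.txt")),
    gene_symbols = readLines(file.path(dir, "gene_symbols.txt")),
    active_mask = if (is.null(man$active_mask)) NULL else unlist(man$active_mask),
    training_log = read_table_tsv(file.path(dir, "training_log.tsv")),
    config = cfg, seed = man$seed), class = "FactorModel")
}
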