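PIPELINE_KEYS <- c("out_dir", "seed", "data", "simulate", "qc", "fit",
                   "summarize", "enrich_regions", "de_regions", "dnm_burden")

#' Run the full analysis pipeline from a YAML config
#'
#' Executes the configured stages in order — simulate (or load) data, QC,
#' factorization, factor summaries, regional detection GLM, regional DE,
#' DNM burden — writing each stage's outputs under `out_dir` and returning a
#' run manifest (config snapshot, seeds, stage timings, md5 checksums of
#' every output file). Stages not present in the config are skipped; later
#' stages reload the outputs of earlier runs from `out_dir`, so a run is
#' resumable stage by stage.
#'
#' @param config path to a YAML config, or an equivalent named list. Top
#'   level keys: `out_dir`, `seed`, and one block per stage (`data` with a
#'   dataset directory may replace `simulate`).
#' @param verbose log stage progress to stderr.
#' @return `RunManifest` list (also written to `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  bad <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(bad)) {
    stop("schema error: unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("schema error: out_dir is required",
                                 call. = FALSE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  timings <- list()
  outputs <- character(0)
  say <- function(...) if (verbose) message("[spanmf] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say(name, " done in ", sprintf("%.1fs", timings[[name]]))
    r
  }

  data <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    data <- stage("simulate", {
      sc_args <- cfg$simulate
      sc_args$seed <- if (is.null(sc_args$seed)) seed else sc_args$seed
      if (!is.null(sc_args$regions)) sc_args$regions <- unlist(sc_args$regions)
      sim <- simulate_dataset(do.call(simulation_config, sc_args))
      truth <- sim$truth
      paths <- write_dataset(sim$data, file.path(out, "dataset"))
      outputs <- c(outputs, paths)
      sim$data
    })
  } else if (!is.null(cfg$data)) {
    data <- stage("load", read_dataset(
      file.path(cfg$data, "counts.mtx"),
      file.path(cfg$data, "cells.tsv"),
      file.path(cfg$data, "panel.tsv")))
  }
  load_data <- function() {
    if (is.null(data)) {
      ddir <- file.path(out, "dataset")
      data <<- read_dataset(file.path(ddir, "counts.mtx"),
                            file.path(ddir, "cells.tsv"),
                            file.path(ddir, "panel.tsv"))
    }
    data
  }

  if (!is.null(cfg$qc)) {
    data <- stage("qc", {
      mt <- cfg$qc$max_transcripts
      if (is.null(mt)) mt <- 1000
      res <- filter_cells(load_data(), max_transcripts = mt)
      p <- write_table(as.data.frame(res$report), file.path(out, "qc_report.tsv"))
      outputs <- c(outputs, p)
      res$data
    })
  }

  model <- NULL
  if (!is.null(cfg$fit)) {
    model <- stage("fit", {
      fc <- cfg$fit
      fc$seed <- if (is.null(fc$seed)) seed else fc$seed
      m <- nmf_fit(load_data(), config = do.call(training_config, fc))
      mask <- select_active_factors(m)
      m <- prune_factors(m, mask)
      write_factor_model(m, file.path(out, "model"))
      outputs <- c(outputs, list.files(file.path(out, "model"),
                                       full.names = TRUE))
      m
    })
  }
  load_model <- function() {
    if (is.null(model)) model <<- read_factor_model(file.path(out, "model"))
    model
  }

  loading_table <- NULL
  if (!is.null(cfg$summarize)) {
    loading_table <- stage("summarize", {
      sz <- cfg$summarize
      d <- load_data(); m <- load_model()
      rs <- region_factor_summary(m, d)
      p1 <- write_table(
        data.frame(region = rownames(rs$mean_counts),
                   rs$mean_counts, check.names = FALSE),
        file.path(out, "region_factor_counts.tsv"))
      p2 <- write_table(
        data.frame(region = rownames(rs$proportions),
                   rs$proportions, check.names = FALSE),
        file.path(out, "region_factor_proportions.tsv"))
      thr <- if (is.null(sz$enrichment_threshold)) 0.33 else sz$enrichment_threshold
      rr <- if (is.null(sz$robust_regions)) sort(unique(d$cells$region_label))
            else unlist(sz$robust_regions)
      rt <- robust_expression_threshold(d[, m$gene_symbols], rr)
      lt <- relative_gene_loading(m, d, enrichment_threshold = thr,
                                  robust_threshold = as.numeric(rt))
      lt <- assign_overlapping_genes(lt)
      p3 <- write_table(as.data.frame(lt), file.path(out, "gene_loadings.tsv"))
      sets <- factor_gene_sets(lt)
      ce <- do.call(rbind, lapply(names(sets), function(s) {
        cbind(gene_set = s,
              suppressWarnings(category_enrichment(sets[[s]], d$genes)))
      }))
      p4 <- if (!is.null(ce)) write_table(ce, file.path(out, "category_enrichment.tsv"))
      outputs <- c(outputs, p1, p2, p3, p4)
      lt
    })
  }

  if (!is.null(cfg$enrich_regions)) {
    stage("enrich_regions", {
      d <- load_data()
      det <- detection_counts(d)
      n_trials <- sum(d$genes$is_susceptibility)
      glm_res <- fit_detection_glm(det, n_trials, d$cells)
      p1 <- write_table(glm_res$regions, file.path(out, "glm_regions.tsv"))
      rk <- rank_regions_by_detection(det, d$cells)
      p2 <- write_table(rk$summary, file.path(out, "region_detection_rank.tsv"))
      outputs <- c(outputs, p1, p2)
      NULL
    })
  }

  if (!is.null(cfg$de_regions)) {
    stage("de_regions", {
      de <- cfg$de_regions
      cap <- if (is.null(de$per_region_cap)) 25000 else de$per_region_cap
      res <- rank_sum_regional_de(load_data(), per_region_cap = cap,
                                  seed = seed)
      p <- write_table(res$table, file.path(out, "de_regions.tsv"))
      outputs <- c(outputs, p)
      NULL
    })
  }

  if (!is.null(cfg$dnm_burden)) {
    stage("dnm_burden", {
      db <- cfg$dnm_burden
      if (!is.null(db$cohort)) {
        sets_df <- read_table_tsv(db$sets)
        sets <- split(sets_df$gene, sets_df$gene_set)
        cohort <- read_dnm_cohort(db$cohort, gene_sets = sets)
      } else {
        # synthetic cohort over the fitted factor gene sets
        if (is.null(loading_table)) {
          stop("dnm_burden needs either a cohort table or a prior summarize stage")
        }
        sets <- factor_gene_sets(loading_table)
        sets <- sets[lengths(sets) > 0]
        genes <- unlist(sets, use.names = FALSE)
        set.seed(seed + 1L)
        rates <- stats::setNames(
          stats::rlnorm(length(genes), log(1e-5), 0.5), genes)
        enr <- if (is.null(db$enrichment)) NULL else unlist(db$enrichment)
        if (!is.null(enr)) enr <- enr[names(sets)]
        cohort <- simulate_dnm_cohort(
          sets, rates,
          n_probands = if (is.null(db$n_probands)) 20000 else db$n_probands,
          enrichment = enr, seed = seed + 2L)
      }
      bt <- dnm_burden_test(cohort)
      p1 <- write_table(bt$burden, file.path(out, "dnm_burden.tsv"))
      p2 <- if (!is.null(bt$pairs)) write_table(bt$pairs,
                                                file.path(out, "dnm_pairs.tsv"))
      outputs <- c(outputs, p1, p2)
      NULL
    })
  }

  outputs <- unique(unname(unlist(outputs)))
  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- sub(paste0("^", out, "/?"), "", names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("spanmf")),
    seed = seed, config = cfg, timings = timings, checksums = checksums)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  structure(manifest, class = "RunManifest")
}
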