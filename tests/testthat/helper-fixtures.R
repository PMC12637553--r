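# Small in-code fixtures shared across tests.

toy_panel <- function(n = 4, categories = NULL) {
  data.frame(
    gene_symbol = paste0("G", seq_len(n)),
    is_susceptibility = rep(TRUE, n),
    is_high_confidence = rep(FALSE, n),
    is_autism_predominant = rep(FALSE, n),
    is_marker = rep(FALSE, n),
    categories = if (is.null(categories)) rep("", n) else categories,
    stringsAsFactors = FALSE)
}

toy_cells <- function(n = 3, region = "thalamus", batch = "section1",
                      individual = "ind1", sex = "F") {
  data.frame(
    cell_id = paste0("c", seq_len(n)),
    x_um = seq_len(n) * 10, y_um = seq_len(n) * 5,
    batch_id = rep_len(batch, n),
    individual_id = rep_len(individual, n),
    sex = rep_len(sex, n),
    region_label = rep_len(region, n),
    system_label = rep_len(region, n),
    stringsAsFactors = FALSE)
}

toy_expression <- function(counts, regions = NULL, batches = "section1") {
  counts <- as.matrix(counts)
  cells <- toy_cells(nrow(counts),
                     region = if (is.null(regions)) "thalamus" else regions,
                     batch = batches)
  ExpressionMatrix(counts, cells, toy_panel(ncol(counts)))
}

# A small simulated dataset reused by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_cells_per_region = 150,
                               regions = c("thalamus", "germinal zones",
                                           "cortical plate"),
                               n_factors_true = 3, n_genes = 30,
                               n_batches = 2, seed = 42)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
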