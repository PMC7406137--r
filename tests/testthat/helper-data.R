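# Shared fixtures, all generated in code.

tiny_counts <- function() {
  tibble::tibble(
    gene_id = c("A|g1", "A|g2", "A|g3"),
    A_maltose_1 = c(10, 100, 0),
    A_maltose_2 = c(12, 90, 0),
    A_avicel_1 = c(50, 95, 3),
    A_avicel_2 = c(55, 105, 4)
  )
}

tiny_info <- function() {
  tibble::tibble(
    sample_id = c("A_maltose_1", "A_maltose_2", "A_avicel_1", "A_avicel_2"),
    species = "A",
    substrate = rep(c("maltose", "avicel"), each = 2),
    replicate = rep(1:2, 2),
    batch = "A"
  )
}

# reduced-size study simulation for fast module tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    n_genes_per_species = 300, n_modules = 4, module_size = 15,
    seed = seed, ...
  )
}

# per-species masking + size factors + log2, as the pipeline runs it
normalize_all <- function(sim) {
  norm <- purrr::imap(sim$counts, function(cnt, sp) {
    masked <- mask_low_counts(cnt, sim$sample_info)
    sf <- size_factors(masked)
    list(
      expr = normalize_log2(masked, sf),
      calls = fold_changes(masked, sf, sim$sample_info)
    )
  })
  list(
    expr_list = purrr::map(norm, "expr"),
    calls = purrr::list_rbind(purrr::map(norm, "calls"))
  )
}

# minimal som_fit with a fixed assignment, for stats/selection arithmetic
fake_som <- function(assignment, units = max(assignment$node)) {
  grid <- lignosom:::hex_grid(1, units)
  structure(
    list(
      codebook = NULL, grid = grid,
      assignment = dplyr::mutate(assignment, row = 1L, col = .data$node),
      units = units, rows = 1L, cols = units,
      n_genes = nrow(assignment)
    ),
    class = "som_fit"
  )
}
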