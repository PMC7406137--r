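#' Select substrate-responsive SOM nodes
#'
#' A node is selected for a substrate when it is highly transcribed there
#' (mean normalized log2 read count >= `high_expr_log2`) or up-regulated
#' (node fold change vs the control >= `fc_threshold`). A node satisfying
#' both rules is reported once per criterion. Empty nodes (`NA` means) are
#' never selected. Raising either threshold can only remove nodes.
#'
#' @param node_stats Node summaries from [node_stats()].
#' @param substrate Substrate of interest.
#' @param config A [filter_config()].
#' @return Tibble `(node, substrate, criterion, n_genes, mean_log2,
#'   fold_change)` with `criterion` in `high_expression`, `up_regulated`.
#' @export
select_responsive <- function(node_stats, substrate, config = filter_config()) {
  if (!substrate %in% node_stats$substrate) {
    abort(paste0("unknown substrate: ", substrate))
  }
  st <- dplyr::filter(node_stats, .data$substrate == !!substrate,
                      .data$n_genes > 0, !is.na(.data$mean_log2))
  high <- st |>
    dplyr::filter(.data$mean_log2 >= config$high_expr_log2) |>
    dplyr::mutate(criterion = "high_expression")
  up <- st |>
    dplyr::filter(.data$fold_change >= config$fc_threshold) |>
    dplyr::mutate(criterion = "up_regulated")
  dplyr::bind_rows(high, up) |>
    dplyr::select("node", "substrate", "criterion", "n_genes",
                  "mean_log2", "fold_change") |>
    dplyr::arrange(.data$node, .data$criterion)
}

#' Select nodes specific to complex lignocellulosic substrates
#'
#' Identifies nodes regulated on the target substrates (wheat straw or
#' aspen by default) but not on the excluded cellulose condition, by either
#' of two criteria applied exactly as printed thresholds:
#' \describe{
#'   \item{specific_i}{mean normalized log2 read count > `high_expr_log2`
#'     on a target substrate AND < `high_expr_log2` on both the control and
#'     every excluded substrate;}
#'   \item{specific_ii}{node fold change vs control >= `fc_threshold` on a
#'     target substrate AND <= `fc_threshold` on every excluded substrate.}
#' }
#' Note the deliberate asymmetry with [select_responsive()]: the
#' high-expression bound here is strict (`>` / `<`), mirroring how the
#' filters are stated.
#'
#' @param node_stats Node summaries from [node_stats()].
#' @param targets Target substrates (default wheat straw and aspen).
#' @param excluded Substrates the node must not respond to (default
#'   avicel, the cellulose-enriched condition).
#' @param config A [filter_config()] (supplies thresholds and the control
#'   substrate name).
#' @return Tibble `(node, substrate, criterion)`: one row per selected node
#'   per satisfying target substrate per criterion.
#' @export
select_specific <- function(node_stats,
                            targets = c("wheat_straw", "aspen"),
                            excluded = "avicel",
                            config = filter_config()) {
  control <- config$control_substrate
  needed <- c(control, excluded, targets)
  missing <- setdiff(needed, unique(node_stats$substrate))
  if (length(missing) > 0) {
    abort(paste0("node_stats misses condition(s): ", paste(missing, collapse = ", ")))
  }
  wide_mean <- tidyr::pivot_wider(
    dplyr::select(node_stats, "node", "substrate", "mean_log2"),
    names_from = "substrate", values_from = "mean_log2"
  )
  wide_fc <- tidyr::pivot_wider(
    dplyr::select(node_stats, "node", "substrate", "fold_change"),
    names_from = "substrate", values_from = "fold_change"
  )
  thr <- config$high_expr_log2
  fct <- config$fc_threshold
  out <- list()
  for (k in seq_len(nrow(wide_mean))) {
    node <- wide_mean$node[k]
    means <- wide_mean[k, ]
    fcs <- wide_fc[k, ]
    if (anyNA(means[needed])) next # empty node
    guard_i <- means[[control]] < thr &&
      all(map_dbl(excluded, ~ means[[.x]]) < thr)
    hits_i <- targets[map_lgl(targets, ~ means[[.x]] > thr)]
    if (guard_i && length(hits_i) > 0) {
      out[[length(out) + 1]] <- tibble(
        node = node, substrate = hits_i, criterion = "specific_i"
      )
    }
    guard_ii <- all(map_dbl(excluded, ~ fcs[[.x]]) <= fct)
    hits_ii <- targets[map_lgl(targets, ~ fcs[[.x]] >= fct)]
    if (guard_ii && length(hits_ii) > 0) {
      out[[length(out) + 1]] <- tibble(
        node = node, substrate = hits_ii, criterion = "specific_ii"
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(node = integer(), substrate = character(),
                  criterion = character()))
  }
  list_rbind(out) |> dplyr::arrange(.data$node, .data$substrate)
}

#' Member genes of a node selection
#'
#' Expands a node selection to its member genes with their functional
#' annotation, sorted by node then family.
#'
#' @param selection Output of [select_responsive()] or [select_specific()].
#' @param som The `som_fit` the selection refers to.
#' @param annotations Gene annotation tibble.
#' @return Tibble `(node, gene_id, species, family, secreted, ssp)`, one
#'   row per member gene of each selected node.
#' @export
genes_of_selection <- function(selection, som, annotations) {
  nodes <- unique(selection$node)
  genes <- som$assignment |>
    dplyr::filter(.data$node %in% nodes) |>
    dplyr::select("node", "gene_id")
  out <- genes |>
    dplyr::left_join(
      dplyr::select(annotations, "gene_id", "species", "family",
                    "secreted", dplyr::any_of("ssp")),
      by = "gene_id"
    )
  if (!"species" %in% names(out) || anyNA(out$species)) {
    out$species <- gene_species(out$gene_id)
  }
  dplyr::arrange(out, .data$node, .data$family, .data$gene_id)
}

#' Recovery of planted modules by a node selection
#'
#' Scores a gene-level selection against simulator truth: sensitivity is
#' the fraction of planted substrate-responsive genes that were selected;
#' the false discovery rate is the fraction of selected genes that were not
#' planted for that substrate.
#'
#' @param selected_genes Gene table from [genes_of_selection()] (or any
#'   tibble with a `gene_id` column).
#' @param truth Gene truth table from [simulate_study()]
#'   (`sim$truth$genes`).
#' @param substrate Substrate whose planted modules are being scored.
#' @return One-row tibble `(substrate, n_planted, n_selected, sensitivity,
#'   fdr)`.
#' @export
recovery_stats <- function(selected_genes, truth, substrate) {
  planted <- truth$gene_id[!is.na(truth$responsive_substrate) &
                             truth$responsive_substrate == substrate]
  sel <- unique(selected_genes$gene_id)
  tibble(
    substrate = substrate,
    n_planted = length(planted),
    n_selected = length(sel),
    sensitivity = if (length(planted) > 0) mean(planted %in% sel) else NA_real_,
    fdr = if (length(sel) > 0) mean(!(sel %in% planted)) else NA_real_
  )
}
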