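#' Validate mass-spectrometry protein identifications
#'
#' An identification is validated when it has at least
#' `min_unique_peptides` unique peptides and a log10 E-value strictly below
#' `max_log_evalue` (defaults: >= 2 peptides and log E < -2.6). Duplicate
#' rows for the same (species, substrate, gene) are collapsed by OR over
#' validation, keeping the best supporting evidence. Validation is
#' deterministic, idempotent, and monotone: tightening either threshold
#' never adds detections.
#'
#' @param secretome Raw MS table (see [read_secretome()]).
#' @param config A [filter_config()].
#' @return Tibble `(species, substrate, gene_id, n_unique_peptides,
#'   log_evalue, detected)` with one row per (species, substrate, gene).
#' @export
#' @examples
#' ms <- tibble::tibble(
#'   species = "A", substrate = "avicel", gene_id = c("A|g1", "A|g2"),
#'   n_unique_peptides = c(2, 1), log_evalue = c(-3, -10)
#' )
#' validate_secretome(ms) # g1 validated; g2 rejected on the peptide rule
validate_secretome <- function(secretome, config = filter_config()) {
  if (any(secretome$n_unique_peptides < 0)) {
    abort("negative unique-peptide counts")
  }
  secretome |>
    dplyr::mutate(
      valid = .data$n_unique_peptides >= config$min_unique_peptides &
        .data$log_evalue < config$max_log_evalue
    ) |>
    dplyr::group_by(.data$species, .data$substrate, .data$gene_id) |>
    dplyr::summarise(
      n_unique_peptides = max(.data$n_unique_peptides),
      log_evalue = min(.data$log_evalue),
      detected = any(.data$valid),
      .groups = "drop"
    )
}

#' Overlay secretome detections on selected nodes
#'
#' Integrates protein detection with the node selection and the gene-level
#' regulation calls: per node, how many member genes are up-regulated and
#' how many of those were detected in the culture medium; globally, the
#' fraction of up-regulated genes (across the selected nodes) whose protein
#' was validated on any tested substrate. When annotations are supplied, a
#' second global fraction restricted to predicted-secreted genes is
#' reported, since only secreted proteins can appear in the medium.
#' Per-substrate detection fractions are emitted alongside.
#'
#' @param selection Node selection from [select_responsive()] or
#'   [select_specific()].
#' @param som The `som_fit` behind the selection.
#' @param evidence Validated detections from [validate_secretome()].
#' @param calls Regulation calls from [fold_changes()].
#' @param annotations Optional annotations (enables the secreted-only
#'   fraction).
#' @return A `secretome_overlay` list: `nodes` (per-node counts), `global`
#'   (one-row fractions) and `per_substrate`; [tidy()] returns the node
#'   table, [glance()] the global row.
#' @export
overlay_nodes <- function(selection, som, evidence, calls,
                          annotations = NULL) {
  nodes <- unique(selection$node)
  members <- som$assignment |>
    dplyr::filter(.data$node %in% nodes) |>
    dplyr::select("node", "gene_id")
  up_genes <- calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(up = any(.data$direction == "up"), .groups = "drop")
  det <- evidence |>
    dplyr::filter(.data$detected) |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::mutate(det_any = TRUE)
  tab <- members |>
    dplyr::left_join(up_genes, by = "gene_id") |>
    dplyr::left_join(det, by = "gene_id") |>
    dplyr::mutate(
      up = dplyr::coalesce(.data$up, FALSE),
      det_any = dplyr::coalesce(.data$det_any, FALSE)
    )
  node_tab <- tab |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$up),
      n_detected = sum(.data$det_any),
      n_up_detected = sum(.data$up & .data$det_any),
      frac_up_detected = ifelse(.data$n_up > 0, .data$n_up_detected / .data$n_up, NA_real_),
      .groups = "drop"
    )
  n_up <- sum(tab$up)
  glob <- tibble(
    n_up = n_up,
    n_up_detected = sum(tab$up & tab$det_any),
    frac_up_detected = if (n_up > 0) sum(tab$up & tab$det_any) / n_up else 0
  )
  if (!is.null(annotations)) {
    sec <- tab |>
      dplyr::left_join(
        dplyr::select(annotations, "gene_id", "secreted"),
        by = "gene_id"
      ) |>
      dplyr::filter(.data$up, dplyr::coalesce(.data$secreted, FALSE))
    glob$n_up_secreted <- nrow(sec)
    glob$frac_up_secreted_detected <-
      if (nrow(sec) > 0) mean(sec$det_any) else 0
  }
  up_ids <- tab$gene_id[tab$up]
  per_sub <- evidence |>
    dplyr::filter(.data$gene_id %in% members$gene_id) |>
    dplyr::group_by(.data$substrate) |>
    dplyr::summarise(
      n_up_detected = sum(.data$detected & .data$gene_id %in% up_ids),
      frac_up_detected = if (length(up_ids) > 0) {
        sum(.data$detected & .data$gene_id %in% up_ids) / length(up_ids)
      } else {
        0
      },
      .groups = "drop"
    )
  structure(
    list(nodes = node_tab, global = glob, per_substrate = per_sub),
    class = "secretome_overlay"
  )
}

#' @export
print.secretome_overlay <- function(x, ...) {
  cat("<secretome_overlay> ", nrow(x$nodes), " selected nodes; ",
      x$global$n_up, " up-regulated genes, ",
      round(100 * x$global$frac_up_detected), "% detected\n", sep = "")
  invisible(x)
}

#' @rdname overlay_nodes
#' @param x A `secretome_overlay`.
#' @param ... Unused.
#' @method tidy secretome_overlay
#' @export
tidy.secretome_overlay <- function(x, ...) x$nodes

#' @rdname overlay_nodes
#' @method glance secretome_overlay
#' @export
glance.secretome_overlay <- function(x, ...) x$global

#' Co-expression / co-secretion report for enzyme family pairs
#'
#' For each requested pair of families (for example manganese peroxidases
#' with glyoxal oxidases, or cellobiose dehydrogenase with AA9 LPMOs),
#' reports whether the two families share SOM nodes (transcriptional
#' co-regulation), on which substrates both have validated protein
#' detections (co-secretion), and whether the two coincide. Co-secretion
#' without a shared node mirrors the biologically meaningful case of
#' enzymes secreted together without transcript-level co-regulation.
#'
#' @param som A `som_fit`.
#' @param evidence Validated detections from [validate_secretome()].
#' @param annotations Gene annotations.
#' @param pairs A list of length-2 character vectors, or a tibble with
#'   columns `family_a`, `family_b`.
#' @return Tibble `(family_a, family_b, n_shared_nodes, shared_nodes,
#'   co_detected_substrates, co_regulated, co_secreted, status)`.
#' @export
coexpression_cosecretion_report <- function(som, evidence, annotations,
                                            pairs) {
  if (is.data.frame(pairs)) {
    pairs <- map2(pairs$family_a, pairs$family_b, c)
  }
  det <- dplyr::filter(evidence, .data$detected) |>
    dplyr::left_join(
      dplyr::select(annotations, "gene_id", "family"),
      by = "gene_id"
    )
  list_rbind(map(pairs, function(p) {
    shared <- suppressWarnings(
      family_conode_query(som, annotations, p[1], p[2])
    )
    subs_a <- unique(det$substrate[det$family == p[1]])
    subs_b <- unique(det$substrate[det$family == p[2]])
    co_subs <- intersect(subs_a, subs_b)
    co_reg <- nrow(shared) > 0
    co_sec <- length(co_subs) > 0
    tibble(
      family_a = p[1], family_b = p[2],
      n_shared_nodes = length(unique(shared$node)),
      shared_nodes = paste(unique(shared$node), collapse = ","),
      co_detected_substrates = paste(sort(co_subs), collapse = ","),
      co_regulated = co_reg,
      co_secreted = co_sec,
      status = dplyr::case_when(
        co_reg & co_sec ~ "co-regulated + co-secreted",
        co_reg ~ "co-regulated only",
        co_sec ~ "co-secreted only",
        .default = "absent"
      )
    )
  }))
}
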