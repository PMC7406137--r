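#' Fold-change matrix over one-to-one orthologs
#'
#' Lays the per-species regulation calls over strict one-to-one
#' orthogroups: each (group, substrate, species) cell carries the member
#' gene's fold change versus the control. A condition absent for one
#' species (for instance a failed culture block) is recorded as a missing
#' cell; the group row is retained. A group member with no regulation call
#' at all is an error.
#'
#' @param calls Regulation calls from [fold_changes()] (bind the species
#'   together first if computed per species).
#' @param groups Long one-to-one orthogroup tibble (see
#'   [one_to_one_groups()]).
#' @return Long tibble `(group_id, substrate, species, gene_id,
#'   fold_change, log2_fc, direction)`.
#' @export
coortholog_fold_matrix <- function(calls, groups) {
  per_sp <- dplyr::count(groups, .data$group_id, .data$species)
  if (any(per_sp$n != 1)) {
    abort("`groups` must be strict one-to-one (use one_to_one_groups())")
  }
  missing <- setdiff(groups$gene_id, unique(calls$gene_id))
  if (length(missing) > 0) {
    abort(paste0(
      length(missing), " orthogroup member gene(s) absent from calls, e.g. ",
      paste(head(missing, 3), collapse = ", ")
    ))
  }
  substrates <- unique(calls$substrate)
  grid <- tidyr::expand_grid(
    groups |> dplyr::select("group_id", "species", "gene_id"),
    substrate = substrates
  )
  grid |>
    dplyr::left_join(
      dplyr::select(calls, "gene_id", "substrate", "fold_change",
                    "log2_fc", "direction"),
      by = c("gene_id", "substrate")
    ) |>
    dplyr::arrange(.data$group_id, .data$substrate, .data$species)
}

#' Conserved regulation across species
#'
#' An orthogroup is conserved-up on a substrate when the member gene of
#' every species has a fold change at or above the threshold, and
#' conserved-down when every fold change is at or below its reciprocal
#' (strict all-species agreement; a missing species cell breaks
#' conservation). Setting `min_species` relaxes the rule to "at least k
#' species agree in direction", matching the pairwise-similarity
#' observation mode.
#'
#' @param fold_matrix Output of [coortholog_fold_matrix()].
#' @param threshold Linear fold-change cutoff (default 4).
#' @param min_species `NULL` for strict all-species conservation, or the
#'   minimum number of agreeing species.
#' @return Tibble `(group_id, substrate, n_species, n_up, n_down,
#'   direction, conserved)` with `direction` in up/down/none.
#' @export
conserved_regulation <- function(fold_matrix, threshold = 4,
                                 min_species = NULL) {
  n_total <- length(unique(fold_matrix$species))
  if (n_total < 2) abort("need calls from at least two species")
  need <- min_species %||% n_total
  fold_matrix |>
    dplyr::group_by(.data$group_id, .data$substrate) |>
    dplyr::summarise(
      n_species = sum(!is.na(.data$fold_change)),
      n_up = sum(.data$fold_change >= threshold, na.rm = TRUE),
      n_down = sum(.data$fold_change <= 1 / threshold, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$n_up >= need ~ "up",
        .data$n_down >= need ~ "down",
        .default = "none"
      ),
      conserved = .data$direction != "none"
    )
}

#' Family-level summary of regulation and conservation
#'
#' Contingency of enzyme family x species: how many genes each family has,
#' how many are up- or down-regulated (on at least one of the given
#' substrates), and the percentage of up-regulated family members.
#' Percentages are truncated toward zero (11/17 reports 64, not 65),
#' matching how such induction percentages are conventionally printed.
#' When conservation results are supplied, a per-family count of conserved
#' orthogroups is returned alongside.
#'
#' @param calls Regulation calls from [fold_changes()].
#' @param annotations Gene annotations (for family labels).
#' @param conserved Optional output of [conserved_regulation()] plus the
#'   orthogroups: pass a list `list(results =, groups =)` or `NULL`.
#' @param substrates Substrates considered (default: all in `calls`).
#' @return A list with `genes` (family x species counts) and `orthogroups`
#'   (per-family conserved group counts, `NULL` when `conserved` is not
#'   given).
#' @export
family_summary <- function(calls, annotations, conserved = NULL,
                           substrates = NULL) {
  substrates <- substrates %||% unique(calls$substrate)
  fam <- dplyr::select(annotations, "gene_id", "species", "family")
  per_gene <- calls |>
    dplyr::filter(.data$substrate %in% substrates) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      up = any(.data$direction == "up"),
      down = any(.data$direction == "down"),
      .groups = "drop"
    )
  genes <- fam |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      up = dplyr::coalesce(.data$up, FALSE),
      down = dplyr::coalesce(.data$down, FALSE)
    ) |>
    dplyr::group_by(.data$family, .data$species) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$up),
      n_down = sum(.data$down),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_up = trunc(100 * .data$n_up / .data$n_genes))
  og <- NULL
  if (!is.null(conserved)) {
    stopifnot(is.list(conserved), all(c("results", "groups") %in% names(conserved)))
    group_family <- conserved$groups |>
      dplyr::left_join(dplyr::select(fam, "gene_id", "family"), by = "gene_id") |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(
        family = names(sort(table(.data$family), decreasing = TRUE))[1],
        .groups = "drop"
      )
    og <- conserved$results |>
      dplyr::filter(.data$conserved) |>
      dplyr::distinct(.data$group_id, .data$direction) |>
      dplyr::left_join(group_family, by = "group_id") |>
      dplyr::count(.data$family, .data$direction, name = "n_conserved_groups")
  }
  list(genes = genes, orthogroups = og)
}

#' Sample-by-sample correlation over co-ortholog genes
#'
#' Builds a cross-species sample correlation matrix by matching genes
#' through strict one-to-one orthogroups: each orthogroup is one row, each
#' sample of every species one column, so samples of different species
#' share a common row space. Pearson correlations are computed for every
#' sample pair; a zero-variance sample yields missing correlations for its
#' pairs.
#'
#' @param expr_list Named list of per-species wide expression tibbles
#'   (typically normalized log2 values).
#' @param sample_info Sample metadata.
#' @param groups Long one-to-one orthogroup tibble covering the species in
#'   `expr_list`.
#' @return Long tibble `(sample_a, sample_b, r, species_a, substrate_a,
#'   species_b, substrate_b)`; symmetric with unit diagonal.
#' @export
sample_correlation <- function(expr_list, sample_info, groups) {
  species <- names(expr_list)
  groups <- one_to_one_groups(groups, species)
  if (nrow(groups) == 0) abort("no one-to-one orthogroups for these species")
  ids <- sort(unique(groups$group_id))
  blocks <- imap(expr_list, function(x, sp) {
    m <- as_expr_matrix(x)
    members <- groups |> dplyr::filter(.data$species == sp)
    found <- members$gene_id %in% rownames(m)
    if (!all(found)) abort(paste0("expression misses orthogroup genes for ", sp))
    mm <- m[members$gene_id[match(ids, members$group_id)], , drop = FALSE]
    rownames(mm) <- ids
    mm
  })
  big <- do.call(cbind, unname(blocks))
  if (ncol(big) < 2) abort("need at least two samples")
  r <- suppressWarnings(cor(big))
  zero_var <- apply(big, 2, sd) == 0
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!zero_var] <- 1
  meta <- sample_info |>
    dplyr::select("sample_id", "species", "substrate")
  as_tibble(r, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r") |>
    dplyr::left_join(meta, by = c(sample_a = "sample_id")) |>
    dplyr::rename(species_a = "species", substrate_a = "substrate") |>
    dplyr::left_join(meta, by = c(sample_b = "sample_id")) |>
    dplyr::rename(species_b = "species", substrate_b = "substrate")
}

#' Nodes where two enzyme families co-occur
#'
#' Finds the SOM nodes containing at least one gene of each of two families
#' -- e.g. cellobiose dehydrogenase together with AA9 LPMOs -- the node-level
#' signature of transcriptional co-regulation between enzymatic partners.
#'
#' @param som A `som_fit`.
#' @param annotations Gene annotations with family labels.
#' @param family_a,family_b Family labels to intersect.
#' @return Tibble `(node, gene_id, species, family)` restricted to the
#'   shared nodes and the two families; zero rows (with a warning for an
#'   unknown family) when there is no shared node.
#' @export
family_conode_query <- function(som, annotations, family_a, family_b) {
  empty <- tibble(node = integer(), gene_id = character(),
                  species = character(), family = character())
  known <- unique(annotations$family)
  for (fam in c(family_a, family_b)) {
    if (!fam %in% known) {
      warn(paste0("unknown family: ", fam))
      return(empty)
    }
  }
  tagged <- som$assignment |>
    dplyr::inner_join(
      dplyr::select(annotations, "gene_id", "species", "family"),
      by = "gene_id"
    ) |>
    dplyr::filter(.data$family %in% c(family_a, family_b))
  shared <- tagged |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      both = any(.data$family == family_a) && any(.data$family == family_b),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$both)
  tagged |>
    dplyr::filter(.data$node %in% shared$node) |>
    dplyr::select("node", "gene_id", "species", "family") |>
    dplyr::arrange(.data$node, .data$family, .data$gene_id)
}
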