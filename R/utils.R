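# Internal helpers shared across modules.

# Wide expression/count tibble (gene_id + one column per sample) -> numeric
# matrix with gene_id rownames.
as_expr_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x))
  if (!"gene_id" %in% names(x)) {
    abort("expected a `gene_id` column in the expression table")
  }
  genes <- x$gene_id
  if (anyDuplicated(genes)) abort("duplicated gene ids in expression table")
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

as_expr_tibble <- function(m) {
  tibble(gene_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(m, .name_repair = "minimal"))
}

#' Species of namespaced gene ids
#'
#' Gene ids are namespaced as `"<species>|<id>"` so that genes from several
#' genomes can live in one table without collisions. This extracts the
#' species prefix.
#'
#' @param gene_id Character vector of namespaced gene ids.
#' @return Character vector of species labels (`NA` where no namespace
#'   separator is present).
#' @export
#' @examples
#' gene_species(c("Pcin|g0001", "Psan|g0042"))
gene_species <- function(gene_id) {
  out <- sub("\\|.*$", "", gene_id)
  out[!grepl("|", gene_id, fixed = TRUE)] <- NA_character_
  out
}

#' @rdname gene_species
#' @param species Species label used as the namespace prefix.
#' @param id Bare within-species gene identifier.
#' @export
make_gene_id <- function(species, id) paste0(species, "|", id)

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# columns of a wide table that are samples (everything except gene_id)
sample_cols <- function(x) setdiff(names(x), "gene_id")

match_sample_info <- function(x, sample_info) {
  cols <- sample_cols(x)
  missing <- setdiff(cols, sample_info$sample_id)
  if (length(missing) > 0) {
    abort(paste0(
      "samples absent from sample_info: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  sample_info[match(cols, sample_info$sample_id), , drop = FALSE]
}
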