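#' Growth substrates of the cross-species culture design
#'
#' Maltose is the non-repressing control; Avicel is the cellulose-enriched
#' substrate; wheat straw, pine and aspen represent grass, softwood and
#' hardwood lignocellulose.
#'
#' @export
study_substrates <- c("maltose", "avicel", "wheat_straw", "pine", "aspen")

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read and write raw count matrices
#'
#' Counts are stored as UTF-8 TSV with a header row of sample ids and gene
#' ids in the first column. Entries must be non-negative integers; duplicate
#' gene or sample ids are a format error.
#'
#' @param path File path.
#' @return `read_counts()` returns a wide tibble with a `gene_id` column
#'   followed by one numeric column per sample.
#' @export
read_counts <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicated sample ids in ", path))
  }
  x <- read_tsv_quiet(path, name_repair = "minimal")
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) abort(paste0("duplicated gene ids in ", path))
  m <- as_expr_matrix(x)
  if (anyNA(m)) abort("missing or non-numeric count entries")
  if (any(m < 0)) abort("negative count entries")
  if (any(m != round(m))) abort("non-integer count entries")
  as_tibble(x)
}

#' @param x Table to write.
#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  stopifnot("gene_id" %in% names(x))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Columns: `sample_id`, `species`, `substrate`, `replicate` and optionally
#' `batch` (defaulting to the species, since each species was sequenced as
#' its own experiment).
#'
#' @param path File path.
#' @param substrates Allowed substrate vocabulary.
#' @return A tibble with one row per sample.
#' @export
read_sample_info <- function(path, substrates = study_substrates) {
  x <- read_tsv_quiet(path)
  needed <- c("sample_id", "species", "substrate", "replicate")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("sample_info misses columns: ", paste(missing, collapse = ", ")))
  }
  if (!"batch" %in% names(x)) x$batch <- x$species
  x$replicate <- as.integer(x$replicate)
  bad <- setdiff(unique(x$substrate), substrates)
  if (length(bad) > 0) {
    abort(paste0("unknown substrates: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(x[c("species", "substrate", "replicate")])) {
    abort("(species, substrate, replicate) must be unique")
  }
  as_tibble(x[c("sample_id", "species", "substrate", "replicate", "batch")])
}

#' @param x Table to write.
#' @rdname read_sample_info
#' @export
write_sample_info <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write gene functional annotations
#'
#' Columns: `gene_id`, `species`, `family` (e.g. `"GH7"`, `"AA9"`,
#' `"AA8-AA3_1 CDH"`), `protein_length` (amino acids), `secreted` (logical)
#' and optionally `ssp`. The `ssp` flag can be (re)derived with
#' [annotate_ssp()].
#'
#' @param path File path.
#' @return A tibble with one row per gene.
#' @export
read_annotations <- function(path) {
  x <- read_tsv_quiet(path)
  needed <- c("gene_id", "species", "family", "protein_length", "secreted")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("annotations miss columns: ", paste(missing, collapse = ", ")))
  }
  x$secreted <- as.logical(x$secreted)
  x$protein_length <- as.numeric(x$protein_length)
  if ("ssp" %in% names(x)) x$ssp <- as.logical(x$ssp)
  as_tibble(x)
}

#' @param x Table to write.
#' @rdname read_annotations
#' @export
write_annotations <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Flag small secreted proteins
#'
#' A gene is a small secreted protein (SSP) when it is predicted secreted
#' and its protein is strictly shorter than `max_len` amino acids. The
#' operation is idempotent and touches no other column.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param max_len SSP length cutoff in amino acids (default 300).
#' @return The annotations with an `ssp` logical column.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   gene_id = c("A|g1", "A|g2"), species = "A", family = "SSP",
#'   protein_length = c(299, 300), secreted = TRUE
#' )
#' annotate_ssp(ann)
annotate_ssp <- function(annotations, max_len = 300) {
  if (anyNA(annotations$protein_length)) {
    abort("protein_length missing for some genes; cannot derive ssp")
  }
  if (anyNA(annotations$secreted)) {
    abort("secreted flag missing for some genes; cannot derive ssp")
  }
  dplyr::mutate(
    annotations,
    ssp = .data$secreted & .data$protein_length < max_len
  )
}

#' Read and write ortholog groups
#'
#' Accepts the OrthoFinder `Orthogroups.tsv` layout: one row per orthogroup,
#' first column the group id, one column per species holding comma-separated
#' gene lists. Orthology is consumed here, never computed. Gene ids are
#' namespaced to `"<species>|<id>"` on ingestion unless already namespaced.
#'
#' @param path File path.
#' @return A long tibble `(group_id, species, gene_id)` with one row per
#'   member gene.
#' @export
read_orthogroups <- function(path) {
  x <- read_tsv_quiet(path)
  names(x)[1] <- "group_id"
  if (anyDuplicated(x$group_id)) abort("duplicated orthogroup ids")
  long <- tidyr::pivot_longer(
    x, -"group_id",
    names_to = "species", values_to = "gene_id"
  ) |>
    dplyr::filter(!is.na(.data$gene_id), .data$gene_id != "") |>
    dplyr::mutate(gene_id = strsplit(.data$gene_id, ",[ ]*")) |>
    tidyr::unnest("gene_id")
  bare <- !grepl("|", long$gene_id, fixed = TRUE)
  long$gene_id[bare] <- make_gene_id(long$species[bare], long$gene_id[bare])
  long
}

#' @param x Long orthogroup tibble as returned by [read_orthogroups()].
#' @rdname read_orthogroups
#' @export
write_orthogroups <- function(x, path) {
  wide <- x |>
    dplyr::group_by(.data$group_id, .data$species) |>
    dplyr::summarise(
      gene_id = paste(sub("^[^|]*\\|", "", .data$gene_id), collapse = ", "),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "species", values_from = "gene_id")
  names(wide)[1] <- "Orthogroup"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Restrict orthogroups to strict one-to-one groups
#'
#' Keeps exactly those orthogroups that have exactly one member gene in
#' every species of `species`; members belonging to other species are
#' dropped from the output. The result is a subset of the input and the
#' operation is idempotent.
#'
#' @param orthogroups Long orthogroup tibble `(group_id, species, gene_id)`.
#' @param species Character vector of species labels that must each be
#'   represented exactly once.
#' @return Filtered long orthogroup tibble.
#' @export
one_to_one_groups <- function(orthogroups, species) {
  if (length(species) == 0) abort("`species` must be non-empty")
  unknown <- setdiff(species, unique(orthogroups$species))
  if (length(unknown) > 0) {
    abort(paste0("unknown species label(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- orthogroups |>
    dplyr::filter(.data$species %in% !!species) |>
    dplyr::count(.data$group_id, .data$species) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      ok = dplyr::n() == length(!!species) && all(.data$n == 1),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok)
  orthogroups |>
    dplyr::filter(
      .data$group_id %in% keep$group_id,
      .data$species %in% !!species
    )
}

#' Read and write secretome identification tables
#'
#' Columns: `species`, `substrate`, `gene_id`, `n_unique_peptides` and
#' `log_evalue` (log10 of the search E-value). If a raw `evalue` column is
#' supplied instead, it is log10-transformed on ingestion.
#'
#' @param path File path.
#' @return A tibble of MS identification rows (pre-validation).
#' @export
read_secretome <- function(path) {
  x <- read_tsv_quiet(path)
  if (!"log_evalue" %in% names(x) && "evalue" %in% names(x)) {
    x$log_evalue <- log10(x$evalue)
    x$evalue <- NULL
  }
  needed <- c("species", "substrate", "gene_id", "n_unique_peptides", "log_evalue")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("secretome table misses columns: ", paste(missing, collapse = ", ")))
  }
  if (any(x$n_unique_peptides < 0)) abort("negative unique-peptide counts")
  as_tibble(x[needed])
}

#' @param x Table to write.
#' @rdname read_secretome
#' @export
write_secretome <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Check the invariants of a full study data set
#'
#' Runs every structural invariant (non-negative integer counts, unique
#' ids, metadata coverage, SSP consistency, orthogroup membership,
#' peptide-count sanity) and reports violations instead of failing at an
#' arbitrary later stage.
#'
#' @param counts Wide count tibble or a named list of per-species count
#'   tibbles.
#' @param sample_info Sample metadata tibble.
#' @param annotations,orthogroups,secretome Optional further tables.
#' @return A tibble `(table, check, message)` of violations; zero rows
#'   means the data set is valid.
#' @export
validate_study <- function(counts, sample_info, annotations = NULL,
                           orthogroups = NULL, secretome = NULL) {
  bad <- list()
  note <- function(table, check, message) {
    bad[[length(bad) + 1]] <<- tibble(table = table, check = check, message = message)
  }
  count_list <- if (is.data.frame(counts)) list(counts = counts) else counts
  for (nm in names(count_list)) {
    m <- as_expr_matrix(count_list[[nm]])
    if (any(m < 0)) note(nm, "nonnegative", "negative count entries")
    if (any(m != round(m))) note(nm, "integer", "non-integer count entries")
    missing <- setdiff(colnames(m), sample_info$sample_id)
    if (length(missing) > 0) {
      note(nm, "metadata", paste0("samples not in sample_info: ", paste(missing, collapse = ", ")))
    }
  }
  if (anyDuplicated(sample_info[c("species", "substrate", "replicate")])) {
    note("sample_info", "unique", "(species, substrate, replicate) not unique")
  }
  if (!is.null(annotations)) {
    if (anyDuplicated(annotations$gene_id)) {
      note("annotations", "unique", "duplicated gene ids")
    }
    if ("ssp" %in% names(annotations)) {
      viol <- annotations$ssp &
        !(annotations$secreted & annotations$protein_length < 300)
      if (any(viol, na.rm = TRUE)) {
        note("annotations", "ssp", "ssp flag set for non-secreted or >=300 aa proteins")
      }
    }
  }
  if (!is.null(orthogroups) && !is.null(annotations)) {
    unknown <- setdiff(orthogroups$gene_id, annotations$gene_id)
    if (length(unknown) > 0) {
      note("orthogroups", "membership",
           paste0(length(unknown), " member genes absent from annotations"))
    }
  }
  if (!is.null(secretome)) {
    if (any(secretome$n_unique_peptides < 0)) {
      note("secretome", "peptides", "negative unique-peptide counts")
    }
  }
  if (length(bad) == 0) {
    tibble(table = character(), check = character(), message = character())
  } else {
    list_rbind(bad)
  }
}
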