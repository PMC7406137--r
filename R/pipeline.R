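#' Configure an end-to-end pipeline run
#'
#' Bundles the simulator (or input file paths), the fixed thresholds, the
#' SOM settings, the output directory and the report queries for one
#' reproducible run of the whole integration pipeline.
#'
#' @param out_dir Output directory; created if absent.
#' @param sim A [sim_config()] for synthetic input, or `NULL` when `paths`
#'   is given.
#' @param paths Optional named list of input files (`counts` = named
#'   character vector of per-species count TSVs, plus `sample_info`,
#'   `annotations`, `orthogroups`, `secretome`).
#' @param filter A [filter_config()].
#' @param som A [som_config()].
#' @param seed Global seed; fanned out to the stages by fixed offsets (the
#'   simulator uses `seed`, SOM training `seed + 101`).
#' @param responsive_substrate Substrate for the responsive-node selection.
#' @param specific_targets,specific_excluded Substrates for the
#'   lignocellulose-specific selection.
#' @param queries Family pairs for the co-expression/co-secretion report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            paths = NULL,
                            filter = filter_config(),
                            som = som_config(),
                            seed = 1L,
                            responsive_substrate = "avicel",
                            specific_targets = c("wheat_straw", "aspen"),
                            specific_excluded = "avicel",
                            queries = list(
                              c("AA8-AA3_1 CDH", "AA9"),
                              c("AA2 MnP", "AA5_1 GLOX")
                            )) {
  if (is.null(sim) && is.null(paths)) {
    abort("either `sim` or `paths` must be supplied")
  }
  if (!is.null(paths)) {
    files <- c(unlist(paths$counts), paths$sample_info, paths$annotations,
               paths$orthogroups, paths$secretome)
    missing <- files[!file.exists(files)]
    if (length(missing) > 0) {
      abort(paste0("input files not found: ", paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(
      out_dir = out_dir, sim = sim, paths = paths, filter = filter,
      som = som, seed = as.integer(seed),
      responsive_substrate = responsive_substrate,
      specific_targets = specific_targets,
      specific_excluded = specific_excluded,
      queries = queries
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("stage ", name, ": ", conditionMessage(e)))
  })
}

#' Run the full integration pipeline
#'
#' Executes simulate (or load) -> per-species normalization -> cross-species
#' combination -> species batch adjustment -> quantile normalization ->
#' SOM clustering -> node selection -> ortholog conservation -> secretome
#' overlay, writing every intermediate artifact as TSV under the output
#' directory together with a `manifest.json` recording the package version,
#' seed, stage parameters and md5 hashes of all outputs. Rerunning with the
#' same configuration reproduces byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fc <- config$filter
  files <- character()
  out <- function(name, x, writer = readr::write_tsv) {
    path <- file.path(config$out_dir, name)
    writer(x, path)
    files[[name]] <<- path
    path
  }

  # --- inputs ------------------------------------------------------------
  dat <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- config$seed
      sim <- simulate_study(sim_cfg)
      out("truth_genes.tsv", sim$truth$genes)
      out("truth_orthogroups.tsv", sim$truth$orthogroups)
      sim
    } else {
      p <- config$paths
      list(
        counts = map(p$counts, read_counts),
        sample_info = read_sample_info(p$sample_info),
        annotations = read_annotations(p$annotations),
        orthogroups = read_orthogroups(p$orthogroups),
        secretome = read_secretome(p$secretome),
        truth = NULL
      )
    }
  })
  for (sp in names(dat$counts)) {
    out(paste0("counts_", sp, ".tsv"), dat$counts[[sp]])
  }
  out("sample_info.tsv", dat$sample_info)
  out("annotations.tsv", dat$annotations)
  out("orthogroups.tsv", dat$orthogroups)
  out("secretome.tsv", dat$secretome)

  # --- per-species normalization ----------------------------------------
  norm <- run_stage("normalize", {
    res <- imap(dat$counts, function(cnt, sp) {
      masked <- mask_low_counts(cnt, dat$sample_info, fc$low_count_mean)
      sf <- size_factors(masked)
      list(
        expr = normalize_log2(masked, sf),
        sf = sf,
        calls = fold_changes(masked, sf, dat$sample_info,
                             control = fc$control_substrate,
                             fc_threshold = fc$fc_threshold)
      )
    })
    res
  })
  for (sp in names(norm)) {
    out(paste0("normalized_", sp, ".tsv"), norm[[sp]]$expr)
    out(paste0("size_factors_", sp, ".tsv"), norm[[sp]]$sf)
  }
  calls <- list_rbind(map(norm, "calls"))
  out("regulation_calls.tsv", calls)

  # --- cross-species harmonization --------------------------------------
  combined <- run_stage("combine", {
    combine_species(map(norm, "expr"), dat$sample_info)
  })
  out("combined.tsv", combined)
  adjusted <- run_stage("batch", adjust_species_batches(combined))
  out("batch_adjusted.tsv", adjusted$expr)
  if (!is.null(adjusted$model)) {
    out("batch_model.tsv", tidy(adjusted$model))
  }
  harmonized <- run_stage("quantile", quantile_normalize(adjusted$expr))
  out("harmonized.tsv", harmonized)

  # --- clustering --------------------------------------------------------
  som <- run_stage("cluster", {
    train_som(harmonized, config$som, seed = config$seed + 101L)
  })
  out("som_codebook.tsv", as_expr_tibble(
    `rownames<-`(som$codebook, paste0("node", seq_len(som$units)))
  ) |> dplyr::rename(node = "gene_id"))
  out("som_assignment.tsv", tidy(som))
  stats <- run_stage("cluster", node_stats(som, harmonized,
                                           control = fc$control_substrate))
  out("node_stats.tsv", stats)

  # --- selection ---------------------------------------------------------
  sel <- run_stage("select", {
    responsive <- select_responsive(stats, config$responsive_substrate, fc)
    specific <- select_specific(stats, config$specific_targets,
                                config$specific_excluded, fc)
    list(responsive = responsive, specific = specific)
  })
  out("selection_responsive.tsv", sel$responsive)
  out("selection_specific.tsv", sel$specific)
  sel_genes <- run_stage("select", {
    genes_of_selection(sel$responsive, som, dat$annotations)
  })
  out("selection_responsive_genes.tsv", sel_genes)

  # --- conservation ------------------------------------------------------
  cons <- run_stage("conserve", {
    groups <- one_to_one_groups(dat$orthogroups, names(dat$counts))
    fm <- coortholog_fold_matrix(calls, groups)
    res <- conserved_regulation(fm, threshold = fc$fc_threshold)
    fam <- family_summary(calls, dat$annotations,
                          conserved = list(results = res, groups = groups))
    list(groups = groups, fold_matrix = fm, results = res, family = fam)
  })
  out("coortholog_fold_matrix.tsv", cons$fold_matrix)
  out("conserved_regulation.tsv", cons$results)
  out("family_summary.tsv", cons$family$genes)
  if (!is.null(cons$family$orthogroups)) {
    out("family_conserved_groups.tsv", cons$family$orthogroups)
  }

  # --- secretome overlay -------------------------------------------------
  overlay <- run_stage("overlay", {
    evidence <- validate_secretome(dat$secretome, fc)
    ov <- overlay_nodes(sel$responsive, som, evidence, calls,
                        annotations = dat$annotations)
    rep <- coexpression_cosecretion_report(som, evidence, dat$annotations,
                                           config$queries)
    list(evidence = evidence, overlay = ov, report = rep)
  })
  out("secretome_evidence.tsv", overlay$evidence)
  out("overlay_nodes.tsv", overlay$overlay$nodes)
  out("overlay_global.tsv", overlay$overlay$global)
  out("overlay_per_substrate.tsv", overlay$overlay$per_substrate)
  out("cosecretion_report.tsv", overlay$report)

  manifest <- list(
    package = "lignosom",
    version = as.character(utils::packageVersion("lignosom")),
    seed = config$seed,
    parameters = list(
      filter = unclass(config$filter),
      som = Filter(Negate(is.null), unclass(config$som)),
      sim = if (!is.null(config$sim)) {
        Filter(Negate(is.null), unclass(config$sim))
      },
      responsive_substrate = config$responsive_substrate,
      specific_targets = config$specific_targets,
      specific_excluded = config$specific_excluded
    ),
    stages = c("input", "normalize", "combine", "batch", "quantile",
               "cluster", "select", "conserve", "overlay"),
    files = as.list(unname(tools::md5sum(unlist(files)))) |>
      setNames(names(files))
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and returns
#' summary tables: node-selection counts, the conserved-family table,
#' secretome detection fractions and, when simulator truth is present,
#' recovery-versus-truth metrics for the responsive selection.
#'
#' @param run_dir Output directory of a completed run.
#' @return A list of tibbles (`selection`, `families`, `detection`, and
#'   `recovery` when truth is available).
#' @export
pipeline_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort("not a completed pipeline run (manifest.json missing)")
  }
  manifest <- jsonlite::read_json(manifest_path)
  need <- function(name) {
    path <- file.path(run_dir, name)
    if (!file.exists(path)) abort(paste0("incomplete run: ", name, " missing"))
    read_tsv_quiet(path)
  }
  responsive <- need("selection_responsive.tsv")
  specific <- need("selection_specific.tsv")
  selection <- dplyr::bind_rows(
    dplyr::mutate(responsive, mode = "responsive"),
    dplyr::mutate(specific, mode = "specific")
  ) |>
    dplyr::group_by(.data$mode, .data$substrate, .data$criterion) |>
    dplyr::summarise(n_nodes = dplyr::n_distinct(.data$node), .groups = "drop")
  out <- list(
    selection = selection,
    families = need("family_summary.tsv"),
    detection = need("overlay_global.tsv")
  )
  truth_path <- file.path(run_dir, "truth_genes.tsv")
  if (file.exists(truth_path)) {
    truth <- read_tsv_quiet(truth_path)
    sel_genes <- need("selection_responsive_genes.tsv")
    substrate <- manifest$parameters$responsive_substrate
    out$recovery <- recovery_stats(sel_genes, truth, substrate)
  }
  out
}
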