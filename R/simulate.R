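#' Configure the multi-omics simulator
#'
#' The simulator emulates the cross-species culture design the pipeline was
#' built for: three wood-decay fungal species grown on five substrates
#' (maltose control, Avicel cellulose, wheat straw, pine, aspen) in
#' biological triplicate, with negative-binomial read counts, species-level
#' batch effects, planted substrate-responsive gene modules partly shared
#' across species through one-to-one orthogroups, and conditional secretome
#' detection for secreted, highly expressed genes. Defaults are the study
#' conditions; [default_study_config()] is an explicit alias.
#'
#' @param species Species labels (batch = species).
#' @param substrates Growth substrates; must include `control_substrate`.
#' @param control_substrate Reference condition (default maltose).
#' @param n_replicates Biological replicates per (species, substrate).
#' @param n_genes_per_species Genes per species; the default 742 matches the
#'   per-species share of a ~2,200-gene curated secretome-relevant set.
#' @param n_modules Planted co-regulated modules per species.
#' @param module_size Genes per module.
#' @param module_fold_change Linear fold change planted on a module's
#'   responsive substrate.
#' @param frac_conserved_modules Fraction of modules whose genes occupy the
#'   same one-to-one orthogroups (and respond identically) in every species.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline expression
#'   (natural-log scale). Orthologous genes share one baseline across
#'   species.
#' @param module_baseline_sd Within-module baseline spread (natural-log
#'   scale). Genes of one planted module share a module-level baseline with
#'   this much gene-to-gene jitter, making modules coherent in expression
#'   level as well as in substrate response -- the signature an
#'   expression-level clustering can recover.
#' @param nb_dispersion Negative-binomial dispersion `alpha` with
#'   `Var = mu + alpha * mu^2`.
#' @param batch_log2_shift,batch_log2_scale Per-species batch effect applied
#'   on the log2 mean: `log2 mu' = shift + scale * log2 mu` (recycled over
#'   species).
#' @param library_size_factors Optional named per-sample size factors; when
#'   `NULL`, drawn log-normal with `sdlog = library_size_sd`.
#' @param library_size_sd Spread of drawn library size factors.
#' @param p_secrete_detect Probability that a secreted gene whose expression
#'   exceeds `detection_log2` is detected by MS on a given substrate.
#' @param detection_log2 Expression threshold (normalized log2 scale) above
#'   which a secreted protein can be detected; defaults to the
#'   high-expression node filter level.
#' @param frac_secreted Fraction of background genes flagged secreted
#'   (module genes encode secreted enzymes by construction).
#' @param p_spurious_ms Rate of sub-threshold MS rows (single-peptide or
#'   weak E-value hits) added to exercise validation.
#' @param drop_blocks Optional tibble `(species, substrate)` of culture
#'   blocks to remove, mimicking a failed RNA extraction.
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = c("Pcin", "Pcoc", "Psan"),
                       substrates = study_substrates,
                       control_substrate = "maltose",
                       n_replicates = 3,
                       n_genes_per_species = 742,
                       n_modules = 8,
                       module_size = 25,
                       module_fold_change = 8,
                       frac_conserved_modules = 0.5,
                       baseline_log_mean = log(300),
                       baseline_log_sd = 1,
                       module_baseline_sd = 0.35,
                       nb_dispersion = 0.1,
                       batch_log2_shift = c(0, 1, -1),
                       batch_log2_scale = 1,
                       library_size_factors = NULL,
                       library_size_sd = 0.25,
                       p_secrete_detect = 0.6,
                       detection_log2 = filter_config()$high_expr_log2,
                       frac_secreted = 0.6,
                       p_spurious_ms = 0.05,
                       drop_blocks = NULL,
                       seed = 1L) {
  if (!control_substrate %in% substrates) {
    abort("`substrates` must include the control substrate")
  }
  if (n_modules * module_size > n_genes_per_species) {
    abort("module_size * n_modules exceeds n_genes_per_species")
  }
  if (n_modules > 0 && length(substrates) < 2) {
    abort("planting modules needs at least one non-control substrate")
  }
  probs <- c(frac_conserved_modules, p_secrete_detect, frac_secreted, p_spurious_ms)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (module_fold_change <= 0) abort("module_fold_change must be > 0")
  structure(
    list(
      species = species, substrates = substrates,
      control_substrate = control_substrate,
      n_replicates = as.integer(n_replicates),
      n_genes_per_species = as.integer(n_genes_per_species),
      n_modules = as.integer(n_modules),
      module_size = as.integer(module_size),
      module_fold_change = module_fold_change,
      frac_conserved_modules = frac_conserved_modules,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      module_baseline_sd = module_baseline_sd,
      nb_dispersion = nb_dispersion,
      batch_log2_shift = rep_len(batch_log2_shift, length(species)),
      batch_log2_scale = rep_len(batch_log2_scale, length(species)),
      library_size_factors = library_size_factors,
      library_size_sd = library_size_sd,
      p_secrete_detect = p_secrete_detect,
      detection_log2 = detection_log2,
      frac_secreted = frac_secreted,
      p_spurious_ms = p_spurious_ms,
      drop_blocks = drop_blocks,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @export
default_study_config <- function(...) sim_config(...)

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", length(x$species), " species x ",
      length(x$substrates), " substrates x ", x$n_replicates,
      " replicates; ", x$n_genes_per_species, " genes/species\n", sep = "")
  cat("  modules: ", x$n_modules, " x ", x$module_size,
      " genes, FC ", x$module_fold_change,
      ", conserved fraction ", x$frac_conserved_modules, "\n", sep = "")
  invisible(x)
}

# family pools used for planted modules, keyed by responsive substrate
module_family_pools <- list(
  avicel      = c("AA9", "GH7", "GH6", "GH5_5", "GH131"),
  wheat_straw = c("AA2 MnP", "AA5_1 GLOX", "GH10", "CE1", "GH12"),
  pine        = c("GH28", "AA1_1", "GH3", "CE16", "GH74"),
  aspen       = c("GH51", "GH16", "AA3_2", "peptidase", "GH27")
)

background_families <- c(
  "GH2", "GH30", "GH31", "GH115", "CE4", "CE8", "CE15", "PL14_4", "GH18",
  "GH76", "GH1", "GH45", "peptidase", "hydrophobin", "SSP", "GST",
  "CYP450", "other"
)

#' Simulate a full cross-species study with planted ground truth
#'
#' Draws raw counts, annotations, orthogroups and an MS secretome table
#' under a known generative model so that every downstream stage of the
#' pipeline can be scored against truth. Counts for gene g in sample j are
#' negative binomial with mean
#' `mu = size_factor_j * 2^(shift_s + scale_s * log2(baseline_g * effect_gs))`
#' where the substrate effect is `module_fold_change` for module genes on
#' their responsive substrate and 1 otherwise.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (named list of per-species wide
#'   count tibbles), `sample_info`, `annotations`, `orthogroups` (long),
#'   `secretome`, `truth` (list of `genes` and `orthogroups` truth tables)
#'   and the `config` used.
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes_per_species = 60, n_modules = 2,
#'                                  module_size = 10, seed = 42))
#' names(sim)
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  S <- length(cfg$species)
  G <- cfg$n_genes_per_species
  ms <- cfg$module_size
  n_mod <- cfg$n_modules
  n_cons <- round(cfg$frac_conserved_modules * n_mod)
  non_control <- setdiff(cfg$substrates, cfg$control_substrate)

  # --- gene layout (identical index layout in every species) -------------
  module_of <- rep(NA_integer_, G)
  if (n_mod > 0) {
    module_of[seq_len(n_mod * ms)] <- rep(seq_len(n_mod), each = ms)
  }
  module_substrate <- if (n_mod > 0) {
    non_control[(seq_len(n_mod) - 1) %% length(non_control) + 1]
  } else {
    character()
  }
  idx_cons_modules <- which(!is.na(module_of) & module_of <= n_cons)
  idx_spec_modules <- which(!is.na(module_of) & module_of > n_cons)
  idx_background <- which(is.na(module_of))
  n_bg_ortho <- floor(0.8 * length(idx_background))
  idx_bg_ortho <- idx_background[seq_len(n_bg_ortho)]
  idx_shared <- c(idx_cons_modules, idx_bg_ortho) # 1-1 orthologs across species
  idx_private <- setdiff(seq_len(G), idx_shared)
  idx_leftover <- setdiff(idx_background, idx_bg_ortho)

  # --- sample metadata ---------------------------------------------------
  sample_info <- tidyr::expand_grid(
    species = cfg$species,
    substrate = cfg$substrates,
    replicate = seq_len(cfg$n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = paste(.data$species, .data$substrate, .data$replicate, sep = "_"),
      batch = .data$species
    ) |>
    dplyr::select("sample_id", "species", "substrate", "replicate", "batch")
  if (!is.null(cfg$drop_blocks)) {
    sample_info <- dplyr::anti_join(
      sample_info, cfg$drop_blocks,
      by = c("species", "substrate")
    )
  }

  sf <- cfg$library_size_factors
  if (is.null(sf)) {
    sf <- setNames(rlnorm(nrow(sample_info), 0, cfg$library_size_sd),
                   sample_info$sample_id)
  } else {
    missing <- setdiff(sample_info$sample_id, names(sf))
    if (length(missing) > 0) abort("library_size_factors must cover all samples")
    sf <- sf[sample_info$sample_id]
  }

  # --- baselines --------------------------------------------------------
  # Orthologous genes share one baseline across species. Module genes share
  # a module-level baseline with within-module jitter so planted modules
  # are coherent in expression level, not only in substrate response;
  # background genes draw independently from the full lognormal.
  baselines <- matrix(NA_real_, nrow = G, ncol = S,
                      dimnames = list(NULL, cfg$species))
  module_base_cons <- rlnorm(n_cons, cfg$baseline_log_mean, cfg$baseline_log_sd)
  if (length(idx_cons_modules) > 0) {
    jitter <- rlnorm(length(idx_cons_modules), 0, cfg$module_baseline_sd)
    baselines[idx_cons_modules, ] <-
      module_base_cons[module_of[idx_cons_modules]] * jitter
  }
  if (length(idx_bg_ortho) > 0) {
    baselines[idx_bg_ortho, ] <-
      rlnorm(length(idx_bg_ortho), cfg$baseline_log_mean, cfg$baseline_log_sd)
  }
  for (s in seq_len(S)) {
    if (length(idx_spec_modules) > 0) {
      base_spec <- rlnorm(n_mod - n_cons, cfg$baseline_log_mean,
                          cfg$baseline_log_sd)
      jitter <- rlnorm(length(idx_spec_modules), 0, cfg$module_baseline_sd)
      baselines[idx_spec_modules, s] <-
        base_spec[module_of[idx_spec_modules] - n_cons] * jitter
    }
    if (length(idx_leftover) > 0) {
      baselines[idx_leftover, s] <-
        rlnorm(length(idx_leftover), cfg$baseline_log_mean, cfg$baseline_log_sd)
    }
  }

  # --- counts ------------------------------------------------------------
  counts <- list()
  for (s in seq_len(S)) {
    sp <- cfg$species[s]
    info_s <- dplyr::filter(sample_info, .data$species == sp)
    effect <- matrix(1, nrow = G, ncol = nrow(info_s))
    if (n_mod > 0) {
      for (m in seq_len(n_mod)) {
        rows <- which(module_of == m)
        cols <- which(info_s$substrate == module_substrate[m])
        if (length(cols) > 0) effect[rows, cols] <- cfg$module_fold_change
      }
    }
    log2mu <- cfg$batch_log2_shift[s] +
      cfg$batch_log2_scale[s] * log2(baselines[, s] * effect)
    mu <- sweep(2^log2mu, 2, sf[info_s$sample_id], `*`)
    cnt <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
      nrow = G
    )
    gene_ids <- make_gene_id(sp, sprintf("g%04d", seq_len(G)))
    counts[[sp]] <- tibble(gene_id = gene_ids) |>
      dplyr::bind_cols(as_tibble(
        `dimnames<-`(cnt, list(NULL, info_s$sample_id)),
        .name_repair = "minimal"
      ))
  }

  # --- annotations -------------------------------------------------------
  ann <- list()
  for (s in seq_len(S)) {
    sp <- cfg$species[s]
    family <- character(G)
    for (i in seq_len(G)) {
      m <- module_of[i]
      if (!is.na(m)) {
        pool <- module_family_pools[[module_substrate[m]]] %||%
          background_families
        k <- i - (m - 1) * ms
        if (m == 1 && m <= n_cons && k == 1 &&
            module_substrate[m] == "avicel") {
          family[i] <- "AA8-AA3_1 CDH" # one CDH gene per genome
        } else {
          family[i] <- pool[(k - 1) %% length(pool) + 1]
        }
      }
    }
    bg_fam <- sample(background_families, length(idx_background), replace = TRUE)
    family[idx_background] <- bg_fam
    secreted <- logical(G)
    secreted[!is.na(module_of)] <- TRUE
    secreted[idx_background] <- runif(length(idx_background)) < cfg$frac_secreted
    secreted[family %in% c("GST", "CYP450", "other")] <- FALSE
    protein_length <- round(runif(G, 100, 1200))
    short <- family %in% c("SSP", "hydrophobin")
    protein_length[short] <- round(runif(sum(short), 80, 299))
    ann[[sp]] <- tibble(
      gene_id = counts[[sp]]$gene_id,
      species = sp,
      family = family,
      protein_length = protein_length,
      secreted = secreted
    )
  }
  annotations <- annotate_ssp(list_rbind(ann))

  # --- orthogroups -------------------------------------------------------
  og_shared <- tidyr::expand_grid(
    idx = idx_shared, species = cfg$species
  ) |>
    dplyr::mutate(
      group_id = sprintf("OG%05d", match(.data$idx, sort(idx_shared))),
      gene_id = make_gene_id(.data$species, sprintf("g%04d", .data$idx))
    ) |>
    dplyr::select("group_id", "species", "gene_id")
  # a few non-1-to-1 groups: first species contributes two paralogs
  n_para <- min(5L, floor(length(idx_leftover) / 2))
  og_para <- NULL
  if (n_para > 0 && S > 1) {
    og_para <- list_rbind(map(seq_len(n_para), function(k) {
      dplyr::bind_rows(
        tibble(
          group_id = sprintf("OGP%02d", k), species = cfg$species[1],
          gene_id = make_gene_id(
            cfg$species[1],
            sprintf("g%04d", idx_leftover[c(2 * k - 1, 2 * k)])
          )
        ),
        tibble(
          group_id = sprintf("OGP%02d", k), species = cfg$species[-1],
          gene_id = make_gene_id(
            cfg$species[-1], sprintf("g%04d", idx_leftover[k])
          )
        )
      )
    }))
  }
  orthogroups <- dplyr::bind_rows(og_shared, og_para) |>
    dplyr::arrange(.data$group_id, .data$species)

  # --- truth -------------------------------------------------------------
  truth_genes <- list_rbind(map(cfg$species, function(sp) {
    tibble(
      gene_id = make_gene_id(sp, sprintf("g%04d", seq_len(G))),
      species = sp,
      module = ifelse(is.na(module_of), NA_character_,
                      paste0("M", module_of)),
      responsive_substrate = ifelse(is.na(module_of), NA_character_,
                                    module_substrate[module_of]),
      fold_change = ifelse(is.na(module_of), 1, cfg$module_fold_change)
    )
  }))
  cons_groups <- unique(og_shared$group_id[
    og_shared$gene_id %in% make_gene_id(
      cfg$species[1], sprintf("g%04d", idx_cons_modules)
    )
  ])
  og_first <- og_shared |>
    dplyr::filter(.data$species == cfg$species[1]) |>
    dplyr::distinct(.data$group_id, .data$gene_id)
  truth_og <- og_first |>
    dplyr::left_join(
      truth_genes |> dplyr::select("gene_id", "module", "responsive_substrate"),
      by = "gene_id"
    ) |>
    dplyr::mutate(conserved = .data$group_id %in% cons_groups) |>
    dplyr::select("group_id", "conserved", "module", "responsive_substrate")

  # --- secretome ---------------------------------------------------------
  sec_rows <- list()
  blocks <- dplyr::distinct(sample_info, .data$species, .data$substrate)
  for (s in seq_len(S)) {
    sp <- cfg$species[s]
    subs <- blocks$substrate[blocks$species == sp]
    sec_idx <- which(annotations$secreted[annotations$species == sp])
    for (sub in subs) {
      eff <- ifelse(
        !is.na(module_of[sec_idx]) & module_substrate[module_of[sec_idx]] == sub,
        cfg$module_fold_change, 1
      )
      expr12 <- log2(baselines[sec_idx, s] * eff + 1)
      detectable <- expr12 >= cfg$detection_log2
      hit <- detectable & runif(length(sec_idx)) < cfg$p_secrete_detect
      spurious <- !hit & runif(length(sec_idx)) < cfg$p_spurious_ms
      if (any(hit)) {
        sec_rows[[length(sec_rows) + 1]] <- tibble(
          species = sp, substrate = sub,
          gene_id = make_gene_id(sp, sprintf("g%04d", sec_idx[hit])),
          n_unique_peptides = 2L + rpois(sum(hit), 3),
          log_evalue = -2.6 - rexp(sum(hit), 0.5)
        )
      }
      if (any(spurious)) {
        n_sp <- sum(spurious)
        one_pep <- runif(n_sp) < 0.5
        sec_rows[[length(sec_rows) + 1]] <- tibble(
          species = sp, substrate = sub,
          gene_id = make_gene_id(sp, sprintf("g%04d", sec_idx[spurious])),
          n_unique_peptides = ifelse(one_pep, 1L, 2L + rpois(n_sp, 1)),
          log_evalue = ifelse(one_pep, -2.6 - rexp(n_sp, 0.5),
                              runif(n_sp, -2.5, -0.5))
        )
      }
    }
  }
  secretome <- if (length(sec_rows) > 0) {
    list_rbind(sec_rows)
  } else {
    tibble(species = character(), substrate = character(),
           gene_id = character(), n_unique_peptides = integer(),
           log_evalue = double())
  }

  list(
    counts = counts,
    sample_info = sample_info,
    annotations = annotations,
    orthogroups = orthogroups,
    secretome = secretome,
    truth = list(genes = truth_genes, orthogroups = truth_og),
    config = cfg
  )
}
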