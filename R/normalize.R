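#' Mask conditions with low mean raw counts
#'
#' Genes whose mean raw read count across the replicates of a growth
#' condition is strictly below `threshold` are treated as not transcribed in
#' that condition and their counts there are set to zero. Masking is applied
#' per (species, substrate) replicate group -- the unit of observation of the
#' design -- so a gene can be silent on one substrate and kept on another.
#' The operation is deterministic and idempotent.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param sample_info Sample metadata covering every count column.
#' @param threshold Mean-count cutoff (strict inequality, default 5).
#' @return The counts with masked entries zeroed.
#' @export
#' @examples
#' cnt <- tibble::tibble(gene_id = "A|g1", s1 = 4, s2 = 4, s3 = 5)
#' info <- tibble::tibble(sample_id = c("s1", "s2", "s3"), species = "A",
#'                        substrate = "avicel", replicate = 1:3, batch = "A")
#' mask_low_counts(cnt, info) # mean 4.33 < 5 -> all zero
mask_low_counts <- function(counts, sample_info, threshold = 5) {
  info <- match_sample_info(counts, sample_info)
  m <- as_expr_matrix(counts)
  groups <- split(seq_len(nrow(info)),
                  paste(info$species, info$substrate, sep = "\r"))
  if (any(lengths(groups) == 0)) abort("condition with zero samples")
  for (cols in groups) {
    low <- rowMeans(m[, cols, drop = FALSE]) < threshold
    m[low, cols] <- 0
  }
  as_expr_tibble(m)
}

#' Median-of-ratios size factors
#'
#' The per-sample normalization constant is the median, over reference
#' genes, of the ratio between the sample's count and the gene's geometric
#' mean across all samples. Reference genes are those with a strictly
#' positive geometric mean, i.e. genes with no zero count in any sample; a
#' gene with a zero anywhere contributes to no median.
#'
#' @param counts Wide count tibble.
#' @return A tibble `(sample_id, size_factor)` with all factors > 0.
#' @export
#' @examples
#' cnt <- tibble::tibble(gene_id = c("g1", "g2"), a = c(2, 8), b = c(4, 16))
#' size_factors(cnt) # sample b is 2x sample a: factors 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  m <- as_expr_matrix(counts)
  log_geo <- rowMeans(log(m))
  ref <- is.finite(log_geo)
  if (!any(ref)) {
    abort("no reference gene: every gene has a zero count in some sample")
  }
  sf <- apply(m[ref, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo[ref]))
  })
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Size-factor normalization and log2 transform
#'
#' Each count is divided by its sample's size factor and log2 transformed
#' with a pseudocount: `log2(count / factor + pseudocount)`. With the
#' default pseudocount of 1, counts masked to zero map to exactly 0.
#'
#' @param counts Wide count tibble.
#' @param factors Size-factor tibble from [size_factors()] (or any tibble
#'   with `sample_id` and `size_factor`).
#' @param pseudocount Added before the log (default 1).
#' @return Wide expression tibble of normalized log2 values.
#' @export
normalize_log2 <- function(counts, factors, pseudocount = 1) {
  m <- as_expr_matrix(counts)
  missing <- setdiff(colnames(m), factors$sample_id)
  if (length(missing) > 0) {
    abort(paste0("no size factor for sample(s): ", paste(missing, collapse = ", ")))
  }
  sf <- factors$size_factor[match(colnames(m), factors$sample_id)]
  if (any(!is.finite(sf) | sf <= 0)) abort("size factors must be > 0")
  as_expr_tibble(log2(sweep(m, 2, sf, `/`) + pseudocount))
}

#' Per-gene fold changes and regulation calls
#'
#' Fold changes compare each substrate with the control, per species, on
#' size-factor-normalized count means:
#' `FC = (mean normalized count on substrate + pseudocount) /
#'       (mean normalized count on control + pseudocount)`.
#' A gene is called `up` when `FC >= fc_threshold`, `down` when
#' `FC <= 1 / fc_threshold`, `none` otherwise -- the |fold change| >= 4
#' rule, with no shrinkage or test statistics, matching how the thresholds
#' are applied downstream.
#'
#' @param counts Wide count tibble (may span several species).
#' @param factors Size-factor tibble covering all samples.
#' @param sample_info Sample metadata.
#' @param control Control substrate (default maltose).
#' @param fc_threshold Linear fold-change cutoff (default 4).
#' @param pseudocount Added to both means (default 1).
#' @return A tibble `(gene_id, species, substrate, control_mean,
#'   substrate_mean, fold_change, log2_fc, direction)` with one row per
#'   gene and non-control substrate.
#' @export
fold_changes <- function(counts, factors, sample_info, control = "maltose",
                         fc_threshold = 4, pseudocount = 1) {
  info <- match_sample_info(counts, sample_info)
  m <- as_expr_matrix(counts)
  sf <- factors$size_factor[match(colnames(m), factors$sample_id)]
  if (anyNA(sf)) abort("size factors must cover all samples")
  norm <- sweep(m, 2, sf, `/`)
  out <- list()
  for (sp in unique(info$species)) {
    ctl_cols <- which(info$species == sp & info$substrate == control)
    if (length(ctl_cols) == 0) {
      abort(paste0("control substrate '", control, "' missing for species ", sp))
    }
    ctl_mean <- rowMeans(norm[, ctl_cols, drop = FALSE])
    for (sub in setdiff(unique(info$substrate[info$species == sp]), control)) {
      cols <- which(info$species == sp & info$substrate == sub)
      sub_mean <- rowMeans(norm[, cols, drop = FALSE])
      fc <- (sub_mean + pseudocount) / (ctl_mean + pseudocount)
      out[[length(out) + 1]] <- tibble(
        gene_id = rownames(norm), species = sp, substrate = sub,
        control_mean = unname(ctl_mean), substrate_mean = unname(sub_mean),
        fold_change = unname(fc), log2_fc = unname(log2(fc)),
        direction = dplyr::case_when(
          fc >= fc_threshold ~ "up",
          fc <= 1 / fc_threshold ~ "down",
          .default = "none"
        )
      )
    }
  }
  list_rbind(out)
}
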