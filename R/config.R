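#' Fixed analysis thresholds
#'
#' One place for every hard threshold used along the pipeline: low-count
#' masking, the high-expression and fold-change node filters, the small
#' secreted protein (SSP) length rule and the mass-spectrometry validation
#' cutoffs.
#'
#' @param low_count_mean Conditions whose mean raw read count across
#'   replicates is strictly below this value are treated as not transcribed
#'   and masked to zero (counts).
#' @param high_expr_log2 Normalized log2 read-count level above which a SOM
#'   node counts as highly transcribed.
#' @param fc_threshold Linear fold-change cutoff (vs the control substrate)
#'   for calling a gene or node regulated.
#' @param ssp_max_len Secreted proteins strictly shorter than this many
#'   amino acids are annotated as SSPs.
#' @param min_unique_peptides Minimum number of unique peptides for a valid
#'   protein identification.
#' @param max_log_evalue Identifications must have log10 E-value strictly
#'   below this (default -2.6).
#' @param control_substrate Reference growth condition all fold changes are
#'   taken against.
#' @return A `filter_config` list.
#' @export
#' @examples
#' filter_config()
filter_config <- function(low_count_mean = 5,
                          high_expr_log2 = 12,
                          fc_threshold = 4,
                          ssp_max_len = 300,
                          min_unique_peptides = 2,
                          max_log_evalue = -2.6,
                          control_substrate = "maltose") {
  pos <- c(
    low_count_mean = low_count_mean, high_expr_log2 = high_expr_log2,
    fc_threshold = fc_threshold, ssp_max_len = ssp_max_len,
    min_unique_peptides = min_unique_peptides
  )
  if (any(pos <= 0)) {
    abort(paste0(
      "thresholds must be strictly positive: ",
      paste(names(pos)[pos <= 0], collapse = ", ")
    ))
  }
  structure(
    list(
      low_count_mean = low_count_mean,
      high_expr_log2 = high_expr_log2,
      fc_threshold = fc_threshold,
      ssp_max_len = ssp_max_len,
      min_unique_peptides = min_unique_peptides,
      max_log_evalue = max_log_evalue,
      control_substrate = control_substrate
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Self-organizing map training settings
#'
#' @param x Map-scaling factor: the number of map units is `x * sqrt(N)` for
#'   `N` genes (default 1.5, which yields about 31-35 genes per node on the
#'   curated gene sets this pipeline targets).
#' @param epochs_multiplier Number of single-gene presentations is this
#'   multiple of the unit count (default 100).
#' @param alpha_start,alpha_end Learning rate, declining linearly over
#'   training.
#' @param radius_quantile The starting neighbourhood radius is this quantile
#'   of all pairwise unit-to-unit distances on the hexagonal grid (default
#'   2/3); it declines linearly to `radius_end`.
#' @param radius_end Final neighbourhood radius (default 0: only the
#'   best-matching unit is updated at the end of training).
#' @param rows,cols Optional explicit grid shape, overriding [map_size()].
#' @param seed Integer seed governing codebook initialization and
#'   presentation order.
#' @return A `som_config` list.
#' @export
som_config <- function(x = 1.5,
                       epochs_multiplier = 100,
                       alpha_start = 0.05,
                       alpha_end = 0.01,
                       radius_quantile = 2 / 3,
                       radius_end = 0,
                       rows = NULL,
                       cols = NULL,
                       seed = 7L) {
  if (x <= 0) abort("`x` must be > 0")
  if (epochs_multiplier <= 0) abort("`epochs_multiplier` must be > 0")
  if (!(alpha_start > alpha_end && alpha_end > 0)) {
    abort("need alpha_start > alpha_end > 0")
  }
  structure(
    list(
      x = x, epochs_multiplier = epochs_multiplier,
      alpha_start = alpha_start, alpha_end = alpha_end,
      radius_quantile = radius_quantile, radius_end = radius_end,
      rows = rows, cols = cols, seed = as.integer(seed)
    ),
    class = "som_config"
  )
}

#' @export
print.som_config <- function(x, ...) {
  cat("<som_config>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
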