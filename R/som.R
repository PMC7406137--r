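#' Size a self-organizing map for a gene set
#'
#' The number of map units follows the standard heuristic
#' `u = x * sqrt(N)` for `N` genes; the rectangle is the near-square
#' decomposition `rows = ceiling(sqrt(u))`, `cols = round(u / rows)` (half
#' away from zero), with at least one column. At the default `x = 1.5` a
#' curated set of 2,227 genes yields a 9 x 8 map of 72 nodes, about 31
#' genes per node.
#'
#' @param n_genes Number of genes (rows of the training matrix).
#' @param x Map-scaling factor (default 1.5).
#' @return One-row tibble `(units, rows, cols)`.
#' @export
#' @examples
#' map_size(2227)       # 72 units on a 9 x 8 grid
#' map_size(100, 1.5)   # 16 units on a 4 x 4 grid
map_size <- function(n_genes, x = 1.5) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    abort("`n_genes` must be a single value >= 1")
  }
  u <- x * sqrt(n_genes)
  rows <- ceiling(sqrt(u))
  cols <- max(1L, as.integer(round_half_away(u / rows)))
  tibble(units = as.integer(rows * cols), rows = as.integer(rows), cols = cols)
}

# Hexagonal offset layout: odd rows are shifted half a unit; vertical pitch
# sqrt(3)/2. Interior units then have exactly six neighbours at distance 1.
hex_grid <- function(rows, cols) {
  g <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  tibble(
    unit = seq_len(nrow(g)),
    row = g$row,
    col = g$col,
    x = g$col + 0.5 * ((g$row - 1) %% 2),
    y = (g$row - 1) * sqrt(3) / 2
  )
}

#' Train a hexagonal self-organizing map on gene expression profiles
#'
#' Online SOM training over genes as observations and individual samples
#' (replicates kept as separate columns) as features. The codebook is
#' initialized by sampling data rows; training performs
#' `epochs_multiplier x units` single-gene presentations in random order.
#' The learning rate declines linearly from `alpha_start` to `alpha_end`
#' and the neighbourhood radius declines linearly from the
#' `radius_quantile` quantile of all unit-to-unit distances to
#' `radius_end`; every unit within the current radius of the best-matching
#' unit (BMU) is moved towards the presented profile (hard neighbourhood).
#' The final gene-to-node assignment is the exact nearest codebook vector
#' under Euclidean distance. Training is deterministic given the seed.
#'
#' @param expr Wide expression tibble (`gene_id` + numeric feature columns)
#'   or a numeric matrix with gene rownames.
#' @param config A [som_config()].
#' @param seed Seed governing initialization and presentation order
#'   (defaults to `config$seed`).
#' @return A `som_fit` object: codebook, hexagonal grid, gene assignment
#'   and quantization error, with [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
train_som <- function(expr, config = som_config(), seed = config$seed) {
  X <- as_expr_matrix(expr)
  if (nrow(X) == 0 || ncol(X) == 0) abort("empty expression matrix")
  if (!all(is.finite(X))) abort("non-finite values in expression matrix")
  n <- nrow(X)

  if (!is.null(config$rows) && !is.null(config$cols)) {
    rows <- config$rows
    cols <- config$cols
  } else {
    sz <- map_size(n, config$x)
    rows <- sz$rows
    cols <- sz$cols
  }
  units <- rows * cols
  if (n < units) {
    warn(paste0("fewer genes (", n, ") than map units (", units, ")"))
  }
  grid <- hex_grid(rows, cols)
  unit_dist <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
  radius_start <- unname(quantile(unit_dist[upper.tri(unit_dist)],
                                  config$radius_quantile))
  n_steps <- ceiling(config$epochs_multiplier * units)

  codebook <- NULL
  withr::with_seed(seed, {
    init <- sample.int(n, units, replace = n < units)
    codebook <- X[init, , drop = FALSE]
    ord <- utils::head(
      unlist(map(seq_len(ceiling(n_steps / n)), function(i) sample.int(n))),
      n_steps
    )
    frac <- if (n_steps > 1) (seq_len(n_steps) - 1) / (n_steps - 1) else 0
    alphas <- config$alpha_start + (config$alpha_end - config$alpha_start) * frac
    radii <- radius_start + (config$radius_end - radius_start) * frac
    nf <- ncol(X)
    for (t in seq_len(n_steps)) {
      xi <- X[ord[t], ]
      diff <- matrix(xi, units, nf, byrow = TRUE) - codebook
      bmu <- which.min(rowSums(diff * diff))
      nb <- which(unit_dist[bmu, ] <= radii[t] + 1e-12)
      codebook[nb, ] <- codebook[nb, , drop = FALSE] +
        alphas[t] * diff[nb, , drop = FALSE]
    }
  })
  rownames(codebook) <- NULL

  assign <- nearest_codebook(X, codebook)
  structure(
    list(
      codebook = codebook,
      grid = grid,
      assignment = tibble(
        gene_id = rownames(X),
        node = assign$unit,
        row = grid$row[assign$unit],
        col = grid$col[assign$unit]
      ),
      features = colnames(X),
      rows = rows, cols = cols, units = units,
      n_genes = n,
      epochs = n_steps,
      radius_start = radius_start,
      quantization_error = mean(assign$dist),
      config = config,
      seed = seed
    ),
    class = "som_fit"
  )
}

# exact nearest-codebook search (ties broken towards the lower unit index)
nearest_codebook <- function(X, codebook) {
  cross <- X %*% t(codebook)
  d2 <- outer(rowSums(X^2), rowSums(codebook^2), `+`) - 2 * cross
  unit <- max.col(-d2, ties.method = "first")
  list(unit = unit, dist = sqrt(pmax(d2[cbind(seq_len(nrow(X)), unit)], 0)))
}

#' @export
print.som_fit <- function(x, ...) {
  cat("<som_fit> ", x$rows, " x ", x$cols, " hexagonal map (", x$units,
      " units), ", x$n_genes, " genes, ", length(x$features), " features\n",
      "  epochs: ", x$epochs, ", quantization error: ",
      signif(x$quantization_error, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname train_som
#' @param x A `som_fit`.
#' @param ... Unused.
#' @method tidy som_fit
#' @export
tidy.som_fit <- function(x, ...) x$assignment

#' @rdname train_som
#' @method glance som_fit
#' @export
glance.som_fit <- function(x, ...) {
  tibble(
    units = x$units, rows = x$rows, cols = x$cols,
    n_genes = x$n_genes, epochs = x$epochs,
    quantization_error = x$quantization_error,
    radius_start = x$radius_start, seed = x$seed
  )
}

#' Node-level expression summaries per substrate
#'
#' For each SOM node and substrate, the mean normalized log2 value over the
#' node's member genes with replicates combined, the node gene count, and
#' the node fold change versus the control substrate. Node means live on
#' the log2 scale, so the linear node fold change is
#' `2^(mean_substrate - mean_control)` (equivalently, the pseudocount-1
#' ratio of the means back-transformed to the linear count scale). Empty
#' nodes get `NA` means and are never selected downstream.
#'
#' @param som A `som_fit`.
#' @param expr The expression tibble the map was trained on (condition
#'   columns as produced by [combine_species()]).
#' @param control Control substrate (default maltose).
#' @return A tibble `(node, substrate, n_genes, mean_log2, log2_fc,
#'   fold_change)`; for the control substrate `log2_fc` is 0.
#' @export
node_stats <- function(som, expr, control = "maltose") {
  stopifnot(inherits(som, "som_fit"))
  m <- as_expr_matrix(expr)
  cond <- condition_info(colnames(m))
  if (!control %in% cond$substrate) {
    abort(paste0("control substrate '", control, "' absent from expression columns"))
  }
  missing <- setdiff(som$assignment$gene_id, rownames(m))
  if (length(missing) > 0) abort("expression matrix misses assigned genes")
  node_of <- som$assignment$node[match(rownames(m), som$assignment$gene_id)]
  stats <- list()
  for (sub in unique(cond$substrate)) {
    cols <- cond$condition[cond$substrate == sub]
    vals <- rowMeans(m[, cols, drop = FALSE])
    agg <- tapply(vals, factor(node_of, levels = seq_len(som$units)), mean)
    cnt <- tabulate(node_of, nbins = som$units)
    stats[[sub]] <- tibble(
      node = seq_len(som$units), substrate = sub,
      n_genes = cnt, mean_log2 = as.numeric(agg)
    )
  }
  out <- list_rbind(stats)
  ctl <- out |>
    dplyr::filter(.data$substrate == control) |>
    dplyr::select("node", ctl_mean = "mean_log2")
  out |>
    dplyr::left_join(ctl, by = "node") |>
    dplyr::mutate(
      log2_fc = .data$mean_log2 - .data$ctl_mean,
      fold_change = 2^.data$log2_fc
    ) |>
    dplyr::select(-"ctl_mean")
}
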