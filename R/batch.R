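#' Combine per-species expression matrices by condition
#'
#' Stacks the genes of several species into one matrix whose columns are
#' aligned growth conditions (`"<substrate>_r<replicate>"`). Column
#' `avicel_r2` holds, for each gene, the value from its own species' second
#' Avicel replicate, so genes from different genomes become comparable rows
#' over a shared condition space. A (species, substrate) block missing from
#' the metadata yields `NA` entries for that species' genes.
#'
#' @param expr_list Named list of per-species wide expression tibbles.
#' @param sample_info Sample metadata covering all samples.
#' @return Wide tibble: `gene_id` plus one column per condition.
#' @seealso [condition_info()] to parse condition columns back into
#'   substrate and replicate.
#' @export
combine_species <- function(expr_list, sample_info) {
  if (is.null(names(expr_list)) || any(names(expr_list) == "")) {
    abort("`expr_list` must be named by species")
  }
  pieces <- imap(expr_list, function(x, sp) {
    info <- match_sample_info(x, sample_info)
    if (!all(info$species == sp)) {
      abort(paste0("samples of table '", sp, "' belong to another species"))
    }
    cond <- paste0(info$substrate, "_r", info$replicate)
    if (anyDuplicated(cond)) abort("duplicated (substrate, replicate) in a species")
    m <- as_expr_matrix(x)
    colnames(m) <- cond
    m
  })
  all_cond <- unique(unlist(map(pieces, colnames)))
  # stable ordering: substrate by first appearance in metadata, then replicate
  ord <- order(
    match(sub("_r\\d+$", "", all_cond), unique(sample_info$substrate)),
    as.integer(sub("^.*_r", "", all_cond))
  )
  all_cond <- all_cond[ord]
  stacked <- map(pieces, function(m) {
    full <- matrix(NA_real_, nrow(m), length(all_cond),
                   dimnames = list(rownames(m), all_cond))
    full[, colnames(m)] <- m
    full
  })
  as_expr_tibble(do.call(rbind, stacked))
}

#' Parse condition column labels
#'
#' @param x A combined expression tibble from [combine_species()] or a
#'   character vector of condition labels.
#' @return A tibble `(condition, substrate, replicate)`.
#' @export
condition_info <- function(x) {
  cond <- if (is.character(x)) x else sample_cols(x)
  ok <- grepl("^.+_r\\d+$", cond)
  if (!all(ok)) {
    abort(paste0("not condition labels: ", paste(head(cond[!ok], 5), collapse = ", ")))
  }
  tibble(
    condition = cond,
    substrate = sub("_r\\d+$", "", cond),
    replicate = as.integer(sub("^.*_r", "", cond))
  )
}

# ---------------------------------------------------------------------------
# Parametric empirical-Bayes location-scale batch adjustment.
#
# dat: features x samples matrix; batch: factor over samples; mod: covariate
# design matrix (samples x q, no intercept) whose effects are protected.
# Follows the standard parametric adjustment: per-feature standardization
# against the full (batch + covariate) OLS fit, normal prior on batch
# locations, inverse-gamma prior on batch scales (moment-matched), iterative
# shrinkage to a fixed point, then back-transformation.
combat_engine <- function(dat, batch, mod = NULL, tol = 1e-4, max_iter = 1000) {
  batch <- droplevels(as.factor(batch))
  n_batch <- nlevels(batch)
  n_array <- ncol(dat)
  batches <- split(seq_len(n_array), batch)
  n_batches <- lengths(batches)
  if (any(n_batches < 2)) {
    abort(paste0("batch with a single sample: ",
                 paste(names(n_batches)[n_batches < 2], collapse = ", ")))
  }

  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- cbind(batch_design, mod)
  if (qr(design)$rank < ncol(design)) {
    abort("batch and covariates are confounded; adjust the design")
  }

  # features that carry no usable variance are passed through unadjusted
  b_hat_all <- solve(crossprod(design), t(design) %*% t(dat))
  resid <- dat - t(design %*% b_hat_all)
  var_pooled_all <- rowMeans(resid^2)
  active <- apply(dat, 1, var) > 0 & var_pooled_all > .Machine$double.eps
  out <- dat
  if (!any(active)) {
    return(list(adjusted = out, model = NULL, active = active))
  }

  d <- dat[active, , drop = FALSE]
  b_hat <- b_hat_all[, active, drop = FALSE]
  var_pooled <- var_pooled_all[active]

  grand_mean <- crossprod(n_batches / n_array,
                          b_hat[seq_len(n_batch), , drop = FALSE])
  stand_mean <- t(grand_mean) %*% matrix(1, 1, n_array)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% b_hat)
  }
  s_data <- (d - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(batch_design),
                       t(batch_design) %*% t(s_data))) # genes x batches
  delta_hat <- do.call(cbind, map(batches, function(cols) {
    apply(s_data[, cols, drop = FALSE], 1, var)
  }))
  colnames(gamma_hat) <- colnames(delta_hat) <- levels(batch)

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  m_d <- colMeans(delta_hat)
  s2_d <- apply(delta_hat, 2, var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(n_batch)
  for (i in seq_len(n_batch)) {
    cols <- batches[[i]]
    n_i <- n_batches[i]
    g_old <- gamma_hat[, i]
    d_old <- delta_hat[, i]
    for (it in seq_len(max_iter)) {
      g_new <- (n_i * t2[i] * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (n_i * t2[i] + d_old)
      sum2 <- rowSums((s_data[, cols, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      change <- max(
        abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
        abs(d_new - d_old) / pmax(abs(d_old), 1e-8)
      )
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    iters[i] <- it
    gamma_star[, i] <- g_old
    delta_star[, i] <- d_old
  }

  adj <- s_data
  for (i in seq_len(n_batch)) {
    cols <- batches[[i]]
    adj[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  out[active, ] <- adj * sqrt(var_pooled) + stand_mean

  model <- structure(
    list(
      feature_ids = rownames(d),
      batch_levels = levels(batch), n_batches = n_batches,
      gamma_hat = gamma_hat, gamma_star = gamma_star,
      delta_hat = delta_hat, delta_star = delta_star,
      gamma_bar = gamma_bar, t2 = t2,
      a_prior = a_prior, b_prior = b_prior,
      grand_mean = drop(grand_mean), var_pooled = var_pooled,
      iterations = iters, tol = tol,
      n_passthrough = sum(!active)
    ),
    class = "batch_model"
  )
  list(adjusted = out, model = model, active = active)
}

#' Empirical-Bayes batch adjustment of an expression matrix
#'
#' Removes additive and multiplicative batch effects from a genes x samples
#' matrix while protecting a biological covariate (by default the growth
#' substrate, since species and substrate are partially confounded in the
#' design). The adjustment is the standard parametric location-scale
#' empirical-Bayes procedure: per-gene standardization preserving covariate
#' effects, a moment-matched normal prior on batch locations and
#' inverse-gamma prior on batch scales, iterative shrinkage to convergence,
#' then back-transformation. Genes that are constant across all samples are
#' passed through unadjusted. A single batch returns the input unchanged.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param sample_info Sample metadata with a batch column.
#' @param batch Name of the batch column (default `"batch"`).
#' @param covariate Name of the covariate column to protect, or `NULL` for
#'   no covariate (default `"substrate"`).
#' @param tol Convergence tolerance on successive shrinkage estimates.
#' @return A list with `expr` (adjusted tibble, same shape and labels) and
#'   `model` (a `batch_model` with [tidy()] and [glance()] methods, or
#'   `NULL` when nothing was adjusted).
#' @export
batch_adjust <- function(expr, sample_info, batch = "batch",
                         covariate = "substrate", tol = 1e-4) {
  info <- match_sample_info(expr, sample_info)
  m <- as_expr_matrix(expr)
  if (anyNA(m)) abort("expression matrix contains missing values")
  b <- as.factor(info[[batch]])
  if (nlevels(droplevels(b)) < 2) {
    return(list(expr = expr, model = NULL))
  }
  mod <- NULL
  if (!is.null(covariate)) {
    f <- as.factor(info[[covariate]])
    if (nlevels(droplevels(f)) > 1) {
      mod <- stats::model.matrix(~f)[, -1, drop = FALSE]
    }
  }
  res <- combat_engine(m, b, mod, tol = tol)
  list(expr = as_expr_tibble(res$adjusted), model = res$model)
}

#' Remove species-level batch effects from a combined cross-species matrix
#'
#' In the combined matrix from [combine_species()] the rows are genes pooled
#' from all species and the columns are shared growth conditions, so the
#' species (sequencing batch) is a property of the rows, not the columns.
#' This applies the same empirical-Bayes location-scale engine as
#' [batch_adjust()] to the transposed matrix: the genes act as the batched
#' observations and the condition columns as features. Per condition, the
#' species-specific location and scale of the gene-expression distribution
#' are equalized; substrate contrasts live across features and are
#' structurally untouched.
#'
#' @param combined Combined wide expression tibble (namespaced gene ids,
#'   condition columns).
#' @param tol Convergence tolerance.
#' @return A list with `expr` (adjusted combined tibble) and `model`
#'   (`batch_model` over condition features).
#' @export
adjust_species_batches <- function(combined, tol = 1e-4) {
  m <- as_expr_matrix(combined)
  if (anyNA(m)) {
    abort(paste0(
      "combined matrix has missing entries (dropped culture blocks?); ",
      "remove incomplete conditions before adjustment"
    ))
  }
  sp <- gene_species(rownames(m))
  if (anyNA(sp)) abort("gene ids must be namespaced '<species>|<id>'")
  if (length(unique(sp)) < 2) {
    return(list(expr = combined, model = NULL))
  }
  res <- combat_engine(t(m), sp, mod = NULL, tol = tol)
  list(expr = as_expr_tibble(t(res$adjusted)), model = res$model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat("<batch_model> ", length(x$feature_ids), " features, batches: ",
      paste0(x$batch_levels, " (n=", x$n_batches, ")", collapse = ", "),
      "\n  shrinkage iterations: ",
      paste(x$iterations, collapse = ", "), " (tol ", x$tol, ")\n", sep = "")
  invisible(x)
}

#' @rdname batch_adjust
#' @param x A `batch_model`.
#' @param ... Unused.
#' @method tidy batch_model
#' @export
tidy.batch_model <- function(x, ...) {
  list_rbind(map(seq_along(x$batch_levels), function(i) {
    tibble(
      feature = x$feature_ids,
      batch = x$batch_levels[i],
      gamma_hat = x$gamma_hat[, i],
      gamma_star = x$gamma_star[, i],
      delta_hat = x$delta_hat[, i],
      delta_star = x$delta_star[, i]
    )
  }))
}

#' @rdname batch_adjust
#' @method glance batch_model
#' @export
glance.batch_model <- function(x, ...) {
  tibble(
    n_features = length(x$feature_ids),
    n_batches = length(x$batch_levels),
    n_passthrough = x$n_passthrough,
    max_iterations = max(x$iterations),
    tol = x$tol
  )
}

#' Quantile normalization across samples
#'
#' Forces every column of the expression matrix onto one common empirical
#' distribution: the vector of row means of the column-wise sorted matrix.
#' Ties within a column receive the mean of the reference quantiles they
#' span. The operation is idempotent and, afterwards, the sorted values of
#' all columns are identical. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param expr Wide expression tibble.
#' @return Quantile-normalized expression tibble of the same shape.
#' @export
#' @examples
#' x <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                     a = c(5, 2, 3), b = c(4, 1, 8))
#' quantile_normalize(x)
quantile_normalize <- function(expr) {
  m <- as_expr_matrix(expr)
  if (anyNA(m)) abort("expression matrix contains missing values")
  if (ncol(m) < 2) return(as_expr_tibble(m))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  as_expr_tibble(out)
}
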