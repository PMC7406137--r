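test_that("quantile normalization matches the hand-worked oracle", {
  x <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      a = c(5, 2, 3), b = c(4, 1, 8))
  out <- quantile_normalize(x)
  expect_equal(out$a, c(6.5, 1.5, 3.5))
  expect_equal(out$b, c(3.5, 1.5, 6.5))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(3)
  m <- matrix(rnorm(60 * 5, 8, 2), 60, 5,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:5)))
  x <- lignosom:::as_expr_tibble(m)
  q1 <- quantile_normalize(x)
  mq <- lignosom:::as_expr_matrix(q1)
  sorted <- apply(mq, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  # identical columns are left untouched
  same <- tibble::tibble(gene_id = c("g1", "g2"), a = c(1, 4), b = c(1, 4))
  expect_equal(quantile_normalize(same), same)
  # single sample is the identity
  one <- tibble::tibble(gene_id = c("g1", "g2"), a = c(2, 9))
  expect_equal(quantile_normalize(one), one)
})

sim_two_batches <- function(seed = 7, p = 500, shift = 3, scale = 1) {
  set.seed(seed)
  substrate <- rep(c("maltose", "avicel", "wheat_straw"), each = 3)
  A <- matrix(rnorm(p * 9, 8, 1), p, 9)
  de <- seq_len(p / 10)
  A[de, substrate == "avicel"] <- A[de, substrate == "avicel"] + 2
  B <- matrix(rnorm(p * 9, 8, scale), p, 9) + shift
  B[de, substrate == "avicel"] <- B[de, substrate == "avicel"] + 2
  m <- cbind(A, B)
  dimnames(m) <- list(paste0("g", 1:p), paste0("s", 1:18))
  info <- tibble::tibble(
    sample_id = colnames(m), species = "A",
    substrate = rep(substrate, 2), replicate = 1:18,
    batch = rep(c("b1", "b2"), each = 9)
  )
  list(expr = lignosom:::as_expr_tibble(m), info = info, de = de, m = m)
}

test_that("batch adjustment matches the sva reference implementation", {
  d <- sim_two_batches()
  res <- batch_adjust(d$expr, d$info)
  mod <- stats::model.matrix(~ d$info$substrate)
  ref <- suppressMessages(sva::ComBat(d$m, batch = d$info$batch, mod = mod))
  expect_equal(lignosom:::as_expr_matrix(res$expr), ref, tolerance = 1e-8)
})

test_that("batch adjustment removes shift and scale while keeping biology", {
  d <- sim_two_batches(seed = 11, p = 1000, shift = 3, scale = 2)
  res <- batch_adjust(d$expr, d$info)
  out <- lignosom:::as_expr_matrix(res$expr)
  # batch-mean gap collapses from 3 to noise level
  gap <- mean(rowMeans(out[, 10:18]) - rowMeans(out[, 1:9]))
  expect_lt(abs(gap), 0.15)
  # the planted substrate effect survives within 15%
  eff <- rowMeans(out[d$de, d$info$substrate == "avicel"]) -
    rowMeans(out[d$de, d$info$substrate == "maltose"])
  expect_lt(abs(median(eff) - 2) / 2, 0.15)
  # a pure scale imbalance (batch B = batch A residuals doubled) is
  # equalized; no covariate structure exists, so none is protected
  set.seed(12)
  p <- 500
  A <- matrix(rnorm(p * 9, 8, 1), p, 9)
  m <- cbind(A, 8 + 2 * (A - 8))
  dimnames(m) <- list(paste0("g", 1:p), paste0("s", 1:18))
  res2 <- batch_adjust(lignosom:::as_expr_tibble(m),
                       dplyr::mutate(d$info[1:18, ], sample_id = colnames(m)),
                       covariate = NULL)
  out2 <- lignosom:::as_expr_matrix(res2$expr)
  v1 <- mean(apply(out2[, 1:9], 1, var))
  v2 <- mean(apply(out2[, 10:18], 1, var))
  expect_lt(abs(v2 / v1 - 1), 0.1)
})

test_that("shrunken batch locations lie between raw estimates and the prior mean", {
  d <- sim_two_batches(seed = 13)
  model <- batch_adjust(d$expr, d$info)$model
  td <- tidy(model)
  for (b in model$batch_levels) {
    tb <- td[td$batch == b, ]
    bar <- model$gamma_bar[b]
    lo <- pmin(tb$gamma_hat, bar) - 1e-10
    hi <- pmax(tb$gamma_hat, bar) + 1e-10
    expect_true(all(tb$gamma_star >= lo & tb$gamma_star <= hi))
    expect_true(all(tb$delta_star > 0))
  }
  expect_equal(glance(model)$n_batches, 2)
})

test_that("degenerate batch designs are handled as specified", {
  d <- sim_two_batches(p = 50)
  # single batch: identity
  info1 <- dplyr::mutate(d$info, batch = "only")
  expect_equal(batch_adjust(d$expr, info1)$expr, d$expr)
  # a batch with one sample is an error
  info2 <- d$info
  info2$batch[18] <- "b3"
  expect_error(batch_adjust(d$expr, info2), "single sample")
  # constant genes pass through unadjusted
  expr3 <- d$expr
  expr3[3, -1] <- 5
  out3 <- batch_adjust(expr3, d$info)$expr
  expect_equal(unlist(out3[3, -1], use.names = FALSE), rep(5, 18))
  # batch fully confounded with the covariate is refused
  info4 <- dplyr::mutate(d$info, batch = ifelse(substrate == "maltose",
                                                "b1", "b2"))
  expect_error(batch_adjust(d$expr, info4), "confounded")
})

test_that("species batch adjustment equalizes per-condition species effects", {
  sim <- simulate_study(small_sim_config(seed = 15,
                                         batch_log2_shift = c(0, 2, -2)))
  norm <- normalize_all(sim)
  comb <- combine_species(norm$expr_list, sim$sample_info)
  m0 <- lignosom:::as_expr_matrix(comb)
  sp <- lignosom:::gene_species(rownames(m0))
  gap0 <- max(abs(tapply(rowMeans(m0), sp, mean) -
                    mean(rowMeans(m0))))
  res <- adjust_species_batches(comb)
  m1 <- lignosom:::as_expr_matrix(res$expr)
  gap1 <- max(abs(tapply(rowMeans(m1), sp, mean) - mean(rowMeans(m1))))
  expect_gt(gap0, 0.5) # the planted species shift is visible before
  expect_lt(gap1, 0.1) # and essentially gone after
  # planted module fold changes survive the adjustment (median over genes)
  cond <- condition_info(res$expr)
  truth <- sim$truth$genes
  mod_avi <- truth$gene_id[!is.na(truth$responsive_substrate) &
                             truth$responsive_substrate == "avicel"]
  lfc <- function(m) {
    rowMeans(m[mod_avi, cond$condition[cond$substrate == "avicel"]]) -
      rowMeans(m[mod_avi, cond$condition[cond$substrate == "maltose"]])
  }
  expect_lt(abs(median(lfc(m1)) / median(lfc(m0)) - 1), 0.15)
})

test_that("missing culture blocks must be resolved before adjustment", {
  sim <- simulate_study(small_sim_config(
    seed = 16, drop_blocks = tibble::tibble(species = "Psan",
                                            substrate = "pine")
  ))
  norm <- normalize_all(sim)
  comb <- combine_species(norm$expr_list, sim$sample_info)
  expect_true(anyNA(comb))
  expect_error(adjust_species_batches(comb), "missing")
  # dropping the incomplete condition restores a complete matrix
  keep <- c("gene_id", condition_info(names(comb)[-1]) |>
              dplyr::filter(substrate != "pine") |>
              dplyr::pull(condition))
  expect_false(anyNA(comb[keep]))
})
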