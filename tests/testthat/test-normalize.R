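test_that("low-count masking zeroes whole conditions on the strict mean rule", {
  cnt <- tibble::tibble(
    gene_id = c("A|g1", "A|g2", "A|g3"),
    m1 = c(4, 5, 0), m2 = c(4, 5, 0), m3 = c(5, 5, 0)
  )
  info <- tibble::tibble(sample_id = c("m1", "m2", "m3"), species = "A",
                         substrate = "maltose", replicate = 1:3, batch = "A")
  out <- mask_low_counts(cnt, info)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(0, 0, 0)) # mean 4.33 < 5
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(5, 5, 5)) # mean 5, kept
  expect_equal(unlist(out[3, -1], use.names = FALSE), c(0, 0, 0)) # all-zero stays
  expect_equal(mask_low_counts(out, info), out) # idempotent
})

test_that("masking is per condition, not global", {
  out <- mask_low_counts(tiny_counts(), tiny_info())
  # g1: maltose mean 11 kept, avicel mean 52.5 kept; g3 avicel mean 3.5 < 5
  expect_equal(out$A_avicel_1, c(50, 95, 0))
  expect_equal(out$A_maltose_1, c(10, 100, 0))
})

test_that("size factors follow the median-of-ratios definition", {
  # identical samples
  cnt <- tibble::tibble(gene_id = c("g1", "g2"), a = c(3, 7), b = c(3, 7))
  expect_equal(size_factors(cnt)$size_factor, c(1, 1))
  # sample b = 2 x sample a: geometric mean splits the factor symmetrically
  cnt2 <- tibble::tibble(gene_id = c("g1", "g2"), a = c(2, 8), b = c(4, 16))
  expect_equal(size_factors(cnt2)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # a gene with a zero anywhere is excluded from the reference set
  cnt3 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         a = c(2, 8, 0), b = c(4, 16, 1000))
  expect_equal(size_factors(cnt3)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # no reference gene at all
  cnt4 <- tibble::tibble(gene_id = c("g1", "g2"), a = c(0, 5), b = c(5, 0))
  expect_error(size_factors(cnt4), "reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(11)
  m <- matrix(rnbinom(200 * 6, mu = 150, size = 8), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  m <- sweep(m, 2, c(0.5, 0.8, 1, 1.2, 1.6, 2), `*`) |> round()
  ours <- size_factors(lignosom:::as_expr_tibble(m))$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("log2 normalization handles zeros and factors exactly", {
  cnt <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        s1 = c(0, 7, 8))
  sf <- tibble::tibble(sample_id = "s1", size_factor = 1)
  out <- normalize_log2(cnt, sf)
  expect_equal(out$s1, c(0, 3, log2(9)))
  sf2 <- tibble::tibble(sample_id = "s1", size_factor = 2)
  expect_equal(normalize_log2(cnt, sf2)$s1[3], log2(5))
  sf_bad <- tibble::tibble(sample_id = "s1", size_factor = 0)
  expect_error(normalize_log2(cnt, sf_bad), "> 0")
  expect_error(normalize_log2(cnt, tibble::tibble(sample_id = "x",
                                                  size_factor = 1)),
               "no size factor")
})

test_that("fold changes apply the pseudocount and the |FC| >= 4 rule", {
  cnt <- tibble::tibble(
    gene_id = c("A|g1", "A|g2", "A|g3"),
    m1 = c(10, 50, 0), m2 = c(10, 50, 0),
    a1 = c(80, 50, 100), a2 = c(80, 50, 100)
  )
  info <- tibble::tibble(
    sample_id = c("m1", "m2", "a1", "a2"), species = "A",
    substrate = rep(c("maltose", "avicel"), each = 2),
    replicate = rep(1:2, 2), batch = "A"
  )
  sf <- tibble::tibble(sample_id = info$sample_id, size_factor = 1)
  out <- fold_changes(cnt, sf, info)
  expect_equal(out$fold_change, c(81 / 11, 1, 101))
  expect_equal(out$direction, c("up", "none", "up"))
  expect_equal(out$log2_fc, log2(out$fold_change))
  # missing control is an error
  info2 <- dplyr::mutate(info, substrate = "avicel",
                         replicate = 1:4)
  expect_error(fold_changes(cnt, sf, info2), "control substrate")
})

test_that("normalized values are invariant to library scaling up to a global constant", {
  set.seed(21)
  m <- matrix(rnbinom(100 * 6, mu = 100, size = 10) + 1, 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  x1 <- lignosom:::as_expr_tibble(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 8 # one library sequenced 8x deeper
  x2 <- lignosom:::as_expr_tibble(m2)
  n1 <- sweep(m, 2, size_factors(x1)$size_factor, `/`)
  n2 <- sweep(m2, 2, size_factors(x2)$size_factor, `/`)
  # scaling one of 6 samples by c rescales every factor by c^(1/6), so the
  # normalized matrices agree after removing that single global constant;
  # all between-sample structure (hence every fold change) is unchanged
  expect_equal(n2 / 8^(1 / 6), n1, tolerance = 1e-9)
  info <- tibble::tibble(sample_id = colnames(m), species = "A",
                         substrate = rep(c("maltose", "avicel"), each = 3),
                         replicate = rep(1:3, 2), batch = "A")
  fc1 <- fold_changes(x1, size_factors(x1), info, pseudocount = 0)
  fc2 <- fold_changes(x2, size_factors(x2), info, pseudocount = 0)
  expect_equal(fc1$fold_change, fc2$fold_change, tolerance = 1e-9)
})
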