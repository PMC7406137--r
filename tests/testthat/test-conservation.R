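calls_for <- function(tbl) {
  # tbl: tibble(species, gene_id, substrate, fold_change)
  dplyr::mutate(tbl,
    log2_fc = log2(.data$fold_change),
    direction = dplyr::case_when(
      fold_change >= 4 ~ "up",
      fold_change <= 0.25 ~ "down",
      .default = "none"
    )
  )
}

three_species_groups <- function(n = 1) {
  purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      group_id = sprintf("G%02d", i),
      species = c("A", "B", "C"),
      gene_id = paste0(c("A", "B", "C"), "|g", i)
    )
  }))
}

test_that("co-ortholog fold matrix lays calls over groups and keeps gaps", {
  groups <- three_species_groups(2)
  calls <- calls_for(tibble::tibble(
    species = rep(c("A", "B", "C"), each = 2),
    gene_id = rep(paste0(c("A", "B", "C"), "|g1"), each = 2),
    substrate = rep(c("avicel", "pine"), 3),
    fold_change = c(4, 2, 4.2, 2, 5.1, 2)
  ))
  # species C has no calls for gene g2 at all -> error
  expect_error(coortholog_fold_matrix(calls, groups), "absent from calls")
  fm <- coortholog_fold_matrix(calls, three_species_groups(1))
  expect_equal(nrow(fm), 6) # 3 species x 2 substrates
  expect_equal(fm$fold_change[fm$substrate == "avicel"], c(4, 4.2, 5.1))
  # a substrate missing for one species is a missing cell, row retained
  calls2 <- dplyr::filter(calls, !(species == "C" & substrate == "pine"))
  fm2 <- coortholog_fold_matrix(calls2, three_species_groups(1))
  expect_equal(sum(is.na(fm2$fold_change)), 1)
  # non one-to-one input is refused
  bad <- dplyr::bind_rows(three_species_groups(1),
                          tibble::tibble(group_id = "G01", species = "A",
                                         gene_id = "A|g9"))
  expect_error(coortholog_fold_matrix(calls, bad), "one-to-one")
})

test_that("conservation requires all species to cross the threshold together", {
  fm <- tibble::tibble(
    group_id = rep(c("G1", "G2", "G3"), each = 3),
    substrate = "avicel",
    species = rep(c("A", "B", "C"), 3),
    gene_id = NA_character_,
    fold_change = c(5.1, 4.4, 8.0,   5.1, 4.4, 1.2,   0.1, 0.2, 0.25),
    log2_fc = NA_real_, direction = NA_character_
  )
  out <- conserved_regulation(fm)
  expect_equal(out$direction, c("up", "none", "down"))
  expect_equal(out$conserved, c(TRUE, FALSE, TRUE))
  # permuting species labels changes nothing
  fm2 <- dplyr::mutate(fm, species = rep(c("C", "A", "B"), 3))
  expect_equal(conserved_regulation(fm2), out)
  # a missing cell breaks strict conservation
  fm3 <- fm
  fm3$fold_change[3] <- NA
  expect_equal(conserved_regulation(fm3)$direction[1], "none")
  # relaxed two-of-three mode recovers it
  expect_equal(conserved_regulation(fm3, min_species = 2)$direction[1], "up")
})

test_that("family summaries count regulated genes with truncated percentages", {
  ann <- tibble::tibble(
    gene_id = c(paste0("A|g", 1:5), paste0("B|g", 1:2)),
    species = c(rep("A", 5), rep("B", 2)),
    family = c(rep("AA9", 3), "GH7", "GH7", "AA9", "GH7")
  )
  calls <- calls_for(tibble::tibble(
    species = "A", gene_id = c("A|g1", "A|g2", "A|g4"),
    substrate = "avicel", fold_change = c(8, 6, 0.1)
  ))
  fs <- family_summary(calls, ann)
  aa9_a <- dplyr::filter(fs$genes, family == "AA9", species == "A")
  expect_equal(aa9_a$n_genes, 3)
  expect_equal(aa9_a$n_up, 2)
  expect_equal(aa9_a$pct_up, trunc(100 * 2 / 3)) # 66, not 67
  gh7_a <- dplyr::filter(fs$genes, family == "GH7", species == "A")
  expect_equal(gh7_a$n_down, 1)
  # marginals: per-species up counts match the calls
  expect_equal(sum(fs$genes$n_up[fs$genes$species == "A"]),
               dplyr::n_distinct(calls$gene_id[calls$direction == "up"]))
  expect_null(fs$orthogroups)
})

test_that("conserved orthogroup counts aggregate by family", {
  groups <- three_species_groups(3)
  ann <- tibble::tibble(gene_id = groups$gene_id, species = groups$species,
                        family = "AA9")
  results <- tibble::tibble(
    group_id = c("G01", "G02", "G03"), substrate = "avicel",
    n_species = 3, n_up = c(3, 3, 0), n_down = 0,
    direction = c("up", "up", "none"), conserved = c(TRUE, TRUE, FALSE)
  )
  fs <- family_summary(
    calls_for(tibble::tibble(species = "A", gene_id = "A|g1",
                             substrate = "avicel", fold_change = 8)),
    ann, conserved = list(results = results, groups = groups)
  )
  expect_equal(fs$orthogroups$n_conserved_groups, 2)
  expect_equal(fs$orthogroups$family, "AA9")
})

test_that("empty inputs give empty, well-formed summaries", {
  ann <- tibble::tibble(gene_id = "A|g1", species = "A", family = "AA9")
  fs <- family_summary(
    calls_for(tibble::tibble(species = character(), gene_id = character(),
                             substrate = character(), fold_change = double())),
    ann
  )
  expect_equal(fs$genes$n_up, 0)
})

test_that("sample correlations behave at the exact and degenerate ends", {
  set.seed(12)
  groups <- three_species_groups(20)
  expr <- purrr::map(
    setNames(c("A", "B", "C"), c("A", "B", "C")),
    function(sp) {
      m <- matrix(rnorm(20 * 3, 8, 2), 20, 3,
                  dimnames = list(paste0(sp, "|g", 1:20),
                                  paste0(sp, "_s", 1:3)))
      lignosom:::as_expr_tibble(m)
    }
  )
  # sample A_s2 duplicates A_s1; A_s3 is the negation of A_s1 around its mean
  expr$A[[3]] <- expr$A[[2]]
  expr$A[[4]] <- 2 * mean(expr$A[[2]]) - expr$A[[2]]
  info <- tibble::tibble(
    sample_id = unlist(purrr::map(c("A", "B", "C"), ~ paste0(.x, "_s", 1:3))),
    species = rep(c("A", "B", "C"), each = 3),
    substrate = rep(c("maltose", "avicel", "pine"), 3),
    replicate = rep(1L, 9), batch = rep(c("A", "B", "C"), each = 3)
  )
  out <- sample_correlation(expr, info, groups)
  r <- function(a, b) out$r[out$sample_a == a & out$sample_b == b]
  expect_equal(r("A_s1", "A_s2"), 1)
  expect_equal(r("A_s1", "A_s3"), -1)
  expect_equal(r("A_s1", "B_s2"), r("B_s2", "A_s1")) # symmetric
  expect_true(all(out$r[out$sample_a == out$sample_b] == 1))
  expect_true(all(abs(out$r) <= 1 + 1e-12))
  # zero-variance sample yields missing correlations
  expr$B[[2]] <- rep(4, 20)
  out2 <- sample_correlation(expr, info, groups)
  expect_true(all(is.na(out2$r[out2$sample_a == "B_s1"])))
})

test_that("family co-occurrence queries find shared nodes", {
  som <- fake_som(tibble::tibble(
    gene_id = paste0("A|g", 1:6), node = c(1L, 1L, 1L, 2L, 2L, 3L)
  ))
  ann <- tibble::tibble(
    gene_id = paste0("A|g", 1:6), species = "A",
    family = c("AA8-AA3_1 CDH", "AA9", "GH7", "AA9", "GH6", "AA2 MnP")
  )
  hit <- family_conode_query(som, ann, "AA8-AA3_1 CDH", "AA9")
  expect_equal(unique(hit$node), 1L)
  expect_setequal(hit$family, c("AA8-AA3_1 CDH", "AA9"))
  none <- family_conode_query(som, ann, "AA2 MnP", "GH7")
  expect_equal(nrow(none), 0)
  expect_warning(out <- family_conode_query(som, ann, "AA9", "nope"),
                 "unknown family")
  expect_equal(nrow(out), 0)
})
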