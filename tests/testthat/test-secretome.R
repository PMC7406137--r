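ms_row <- function(gene, pep, loge, substrate = "avicel", species = "A") {
  tibble::tibble(species = species, substrate = substrate, gene_id = gene,
                 n_unique_peptides = pep, log_evalue = loge)
}

test_that("validation applies both thresholds with the stated strictness", {
  ms <- dplyr::bind_rows(
    ms_row("A|g1", 2, -3.0),   # both met at the peptide boundary
    ms_row("A|g2", 1, -10.0),  # fails the peptide rule
    ms_row("A|g3", 5, -2.6),   # log E not strictly below -2.6
    ms_row("A|g4", 3, -2.61)   # just below: validated
  )
  out <- validate_secretome(ms)
  det <- setNames(out$detected, out$gene_id)
  expect_equal(unname(det[paste0("A|g", 1:4)]), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(validate_secretome(ms_row("A|g1", -1, -5)), "negative")
})

test_that("duplicates collapse by OR and validation is monotone in thresholds", {
  ms <- dplyr::bind_rows(
    ms_row("A|g1", 1, -9), ms_row("A|g1", 4, -8), # one valid row suffices
    ms_row("A|g2", 2, -3), ms_row("A|g3", 2, -2.7)
  )
  out <- validate_secretome(ms)
  expect_equal(nrow(out), 3)
  expect_true(out$detected[out$gene_id == "A|g1"])
  stricter <- validate_secretome(ms, filter_config(min_unique_peptides = 3,
                                                   max_log_evalue = -5))
  expect_true(all(stricter$gene_id[stricter$detected] %in%
                    out$gene_id[out$detected]))
  # deterministic / idempotent
  expect_equal(validate_secretome(ms), out)
})

test_that("overlay arithmetic matches hand counts", {
  som <- fake_som(tibble::tibble(gene_id = paste0("A|g", 1:12),
                                 node = rep(c(1L, 2L), each = 6)))
  sel <- tibble::tibble(node = c(1L, 2L), substrate = "avicel",
                        criterion = "up_regulated")
  calls <- tibble::tibble(
    gene_id = paste0("A|g", 1:12), species = "A", substrate = "avicel",
    fold_change = c(rep(8, 10), 1, 1),
    log2_fc = log2(fold_change),
    direction = c(rep("up", 10), "none", "none")
  )
  ev <- validate_secretome(purrr::list_rbind(
    purrr::map(paste0("A|g", 1:5), ~ ms_row(.x, 3, -5))
  ))
  ov <- overlay_nodes(sel, som, ev, calls)
  expect_equal(glance(ov)$n_up, 10)
  expect_equal(glance(ov)$frac_up_detected, 0.5) # 5 of 10 up genes detected
  expect_equal(sum(tidy(ov)$n_up_detected), 5)
  # no detections at all
  ov0 <- overlay_nodes(sel, som, ev[0, ], calls)
  expect_equal(glance(ov0)$frac_up_detected, 0)
})

test_that("detection fraction tracks the planted detection probability", {
  # same seed, p = 1 marks exactly the detectable set (identical RNG stream),
  # so the p = 0.6 run should detect ~60% of it
  full <- simulate_study(sim_config(seed = 20, p_secrete_detect = 1))
  part <- simulate_study(sim_config(seed = 20, p_secrete_detect = 0.6))
  detectable <- unique(dplyr::filter(validate_secretome(full$secretome),
                                     detected)$gene_id)
  detected <- unique(dplyr::filter(validate_secretome(part$secretome),
                                   detected)$gene_id)
  expect_true(all(detected %in% detectable))
  expect_lt(abs(length(detected) / length(detectable) - 0.6), 0.1)

  # the overlay's global fraction then matches p x detectable share of the
  # up-regulated genes in the selected nodes
  norm <- normalize_all(part)
  comb <- combine_species(norm$expr_list, part$sample_info)
  harm <- quantile_normalize(adjust_species_batches(comb)$expr)
  som <- train_som(harm, som_config(), seed = 22)
  st <- node_stats(som, harm)
  sel <- select_responsive(st, "avicel")
  ov <- overlay_nodes(sel, som, validate_secretome(part$secretome),
                      norm$calls)
  members <- som$assignment$gene_id[som$assignment$node %in% sel$node]
  up_ids <- unique(norm$calls$gene_id[norm$calls$direction == "up"])
  up_sel <- intersect(members, up_ids)
  expected <- 0.6 * mean(up_sel %in% detectable)
  expect_lt(abs(glance(ov)$frac_up_detected - expected), 0.1)
})

test_that("co-secretion report distinguishes co-regulation from co-detection", {
  som <- fake_som(tibble::tibble(
    gene_id = paste0("A|g", 1:4), node = c(1L, 1L, 2L, 3L)
  ))
  ann <- tibble::tibble(
    gene_id = paste0("A|g", 1:4), species = "A",
    family = c("AA2 MnP", "AA5_1 GLOX", "AA9", "GH7"),
    protein_length = 500, secreted = TRUE, ssp = FALSE
  )
  ev <- validate_secretome(dplyr::bind_rows(
    ms_row("A|g1", 3, -5, substrate = "aspen"),
    ms_row("A|g2", 3, -5, substrate = "aspen"),
    ms_row("A|g3", 3, -5, substrate = "avicel")
  ))
  rep1 <- coexpression_cosecretion_report(som, ev, ann,
                                          list(c("AA2 MnP", "AA5_1 GLOX")))
  expect_equal(rep1$status, "co-regulated + co-secreted")
  expect_equal(rep1$co_detected_substrates, "aspen")
  # detected together but in different nodes: co-secreted only
  som2 <- fake_som(tibble::tibble(
    gene_id = paste0("A|g", 1:4), node = c(1L, 2L, 2L, 3L)
  ))
  ev2 <- validate_secretome(dplyr::bind_rows(
    ms_row("A|g1", 3, -5, substrate = "aspen"),
    ms_row("A|g2", 3, -5, substrate = "aspen")
  ))
  rep2 <- coexpression_cosecretion_report(som2, ev2, ann,
                                          list(c("AA2 MnP", "AA5_1 GLOX")))
  expect_equal(rep2$status, "co-secreted only")
  # empty secretome: co-regulation at best
  rep3 <- coexpression_cosecretion_report(som, ev[0, ], ann,
                                          list(c("AA2 MnP", "AA5_1 GLOX"),
                                               c("AA9", "GH7")))
  expect_equal(rep3$status, c("co-regulated only", "absent"))
})
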