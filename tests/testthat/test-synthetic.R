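small_config <- function(conditions_per_drug = 3, ...) {
  synthetic_config(
    n_genes = 100, n_up = 10, n_down = 10, n_drugs = 12,
    class_sizes = c("G9a inhibitor" = 6, "BTK inhibitor" = 6),
    planted_reverser_classes = "G9a inhibitor",
    planted_mimic_classes = character(0),
    sensitive_classes = "G9a inhibitor",
    resistant_classes = character(0),
    n_discriminating = 0, conditions_per_drug = conditions_per_drug,
    seed = 1, ...)
}

test_that("DE tables carry exactly the planted pass counts", {
  cfg <- small_config()
  de <- generate_de_table(cfg)
  th <- signature_thresholds()
  up_pass <- de$table$fdr <= 0.05 & de$table$log2fc >= 0.5
  dn_pass <- de$table$fdr <= 0.05 & de$table$log2fc <= -0.5
  expect_identical(sum(up_pass), 10L)
  expect_identical(sum(dn_pass), 10L)
  expect_setequal(de$table$gene[up_pass], de$truth$planted_up)
  expect_setequal(de$table$gene[dn_pass], de$truth$planted_down)
  # the same rows also pass in linear fold-change mode
  fc_pass <- de$table$fdr <= 0.05 &
    (de$table$fc >= 1.2 | de$table$fc <= 0.8)
  expect_identical(sum(fc_pass), 20L)

  none <- generate_de_table(synthetic_config(n_genes = 50, n_up = 0, n_down = 0,
                                             n_drugs = 12,
                                             class_sizes = c(a = 6, b = 6),
                                             planted_reverser_classes = "a",
                                             planted_mimic_classes = character(0),
                                             sensitive_classes = "a",
                                             resistant_classes = character(0),
                                             n_discriminating = 0))
  expect_identical(sum(none$table$fdr <= 0.05 & abs(none$table$log2fc) >= 0.5), 0L)
})

test_that("re-seeding with fixed planted sets changes nulls only", {
  cfg <- small_config()
  de1 <- generate_de_table(cfg, seed = 1)
  de2 <- generate_de_table(cfg, seed = 2,
                           planted = list(up = de1$truth$planted_up,
                                          down = de1$truth$planted_down))
  expect_identical(de2$truth, de1$truth)
  null_genes <- setdiff(de1$table$gene, c(de1$truth$planted_up,
                                          de1$truth$planted_down))
  f1 <- de1$table$fdr[match(null_genes, de1$table$gene)]
  f2 <- de2$table$fdr[match(null_genes, de2$table$gene)]
  expect_false(any(f1 == f2))
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- small_config()
  sig <- disease_signature(up = sprintf("G%04d", 1:5),
                           down = sprintf("G%04d", 6:10))
  p1 <- generate_profiles(cfg, sig)
  p2 <- generate_profiles(cfg, sig)
  expect_identical(p1, p2)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1, s2)
})

test_that("full-strength noiseless reversers rank disease-up genes at the bottom", {
  cfg <- small_config(reversal_strength = 1, noise_sd = 0)
  sig <- disease_signature(up = sprintf("G%04d", 1:10),
                           down = sprintf("G%04d", 11:20))
  gen <- generate_profiles(cfg, sig)
  rev_drugs <- gen$truth$reverser_drugs
  expect_length(rev_drugs, 6)
  prof <- gen$profiles[gen$profiles$drug == rev_drugs[1] &
                         gen$profiles$dose_uM == 10, ]
  ranked <- prof$gene[order(-prof$fc, prof$gene, method = "radix")]
  expect_setequal(ranked[91:100], sig$up)    # all up genes in bottom 10
  expect_setequal(ranked[1:10], sig$down)    # all down genes on top
})

test_that("each drug receives the configured number of distinct conditions", {
  cfg <- small_config()
  sig <- disease_signature(up = "G0001", down = "G0002")
  gen <- generate_profiles(cfg, sig)
  keys <- unique(paste(gen$profiles$drug, gen$profiles$cell_line,
                       gen$profiles$dose_uM, gen$profiles$time_h))
  expect_identical(length(keys), 12L * 3L)
  per_drug <- table(sub(" .*", "", keys))
  expect_true(all(per_drug == 3))
  expect_error(generate_profiles(cfg, disease_signature(character(0),
                                                        character(0))),
               class = "revsig_data_error")
})

test_that("zero reversal strength makes planted drugs indistinguishable", {
  cfg <- small_config(reversal_strength = 0, conditions_per_drug = 1)
  sig <- disease_signature(up = sprintf("G%04d", 1:10),
                           down = sprintf("G%04d", 11:20))
  diffs <- vapply(1:50, function(s) {
    gen <- generate_profiles(cfg, sig, seed = s)
    rg <- rges_table(gen$profiles, sig)
    planted <- rg$drug %in% gen$truth$reverser_drugs
    mean(rg$rges[planted]) - mean(rg$rges[!planted])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("the screen uses the five stated concentrations for every drug/genotype", {
  cfg <- small_config()
  scr <- generate_screen(cfg)
  treated <- scr$plates[scr$plates$role == "treated", ]
  per <- dplyr::distinct(treated, .data$drug, .data$genotype, .data$dose_uM) |>
    dplyr::count(.data$drug, .data$genotype)
  expect_true(all(per$n == 5L))
  expect_setequal(unique(treated$dose_uM), c(0.05, 0.2, 1, 2, 5))
  # every plate carries both control types
  roles <- table(scr$plates$plate, scr$plates$role)
  expect_true(all(roles[, "dmso"] >= 1 & roles[, "empty"] >= 1))
})

test_that("noiseless screen refit recovers the planted 4-fold sensitization", {
  cfg <- small_config(screen_noise_sd = 0, screen_replicates = 1)
  scr <- generate_screen(cfg)
  viab <- normalize_plates(scr$plates)
  phen <- screen_phenotypes(viab)
  sens <- phen[phen$drug %in% scr$truth$sensitive_drugs, ]
  fitted <- sens[sens$basis == "ic50_ratio", ]
  expect_gt(nrow(fitted), 0)
  expect_equal(fitted$response_fc, rep(0.25, nrow(fitted)), tolerance = 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 10, n_up = 8, n_down = 8),
               class = "revsig_config_error")
  expect_error(synthetic_config(reversal_strength = 1.2),
               class = "revsig_config_error")
  expect_error(synthetic_config(class_sizes = c(a = 100)),
               class = "revsig_config_error")
  expect_error(synthetic_config(planted_reverser_classes = "nope"),
               class = "revsig_config_error")
})
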