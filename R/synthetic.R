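# Synthetic-data module: generates every pipeline input with known planted
# truth (differential-expression tables, drug-response profiles with planted
# reverser/mimic classes, MOA annotation, a plate-based viability screen
# with planted sensitization) so that every downstream stage is testable
# without external databases.

#' Configuration of the synthetic dataset
#'
#' Collects every knob of the synthetic-data generator, with defaults that
#' emulate a desk-scale version of a connectivity-map drug-repurposing
#' study: a 1000-gene universe, a 100+100-gene disease signature, 60 drugs
#' in six 10-member MOA classes measured under 3 conditions each, one
#' planted reverser class and one planted disease-mimicking class, two
#' phenotype-sensitive classes (4-fold IC50 sensitization in the mutant
#' genotype), and a 96-well screen at the five concentrations
#' 0.05/0.2/1/2/5 uM.
#'
#' @param n_genes Gene-universe size.
#' @param n_up,n_down Planted signature sizes (`n_up + n_down <= n_genes`).
#' @param n_drugs Number of drugs.
#' @param class_sizes Named integer vector of MOA class sizes (sum
#'   `<= n_drugs`; drugs beyond the sum stay unannotated).
#' @param planted_reverser_classes Classes whose drugs reverse the disease
#'   signature.
#' @param planted_mimic_classes Classes whose drugs mimic the disease
#'   signature (forced fold-changes with the disease sign).
#' @param sensitive_classes Classes sensitized in the mutant genotype (and
#'   carrying the planted discriminating reversal genes).
#' @param resistant_classes Classes de-sensitized in the mutant genotype.
#' @param n_discriminating Number of signature genes reversed only by the
#'   sensitive classes (the planted sensitivity-discriminating reversal
#'   genes).
#' @param reversal_strength Fraction in \[0, 1\] of signature genes whose
#'   sign is forced in planted reverser/mimic profiles.
#' @param effect_size Mean magnitude of forced fold-changes (log2 units).
#' @param conditions_per_drug Number of (cell line, dose, time) conditions
#'   per drug.
#' @param noise_sd Standard deviation of the null fold-change noise.
#' @param cell_lines Cell-line labels cycled over conditions.
#' @param screen_doses Screen concentrations in uM.
#' @param screen_replicates Replicate plates per genotype.
#' @param genotypes Genotype labels, `c(wild_type, mutant)`.
#' @param sensitivity_fc IC50 fold-sensitization of sensitive drugs in the
#'   mutant genotype (and fold-resistance of resistant drugs).
#' @param dmso_mean,empty_mean Plate control signal means (arbitrary
#'   units; `dmso_mean > empty_mean`).
#' @param screen_noise_sd Additive signal noise on the plates.
#' @param ic50_meanlog,ic50_sdlog Log-normal parameters of the wild-type
#'   IC50 distribution (uM).
#' @param seed Default seed for all generators.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 1000, n_up = 100, n_down = 100,
                             n_drugs = 60,
                             class_sizes = c("G9a inhibitor" = 10,
                                             "HDAC class I inhibitor" = 10,
                                             "BET inhibitor" = 10,
                                             "ATM/ATR inhibitor" = 10,
                                             "BTK inhibitor" = 10,
                                             "topoisomerase inhibitor" = 10),
                             planted_reverser_classes = "G9a inhibitor",
                             planted_mimic_classes = "topoisomerase inhibitor",
                             sensitive_classes = c("G9a inhibitor",
                                                   "HDAC class I inhibitor"),
                             resistant_classes = "topoisomerase inhibitor",
                             n_discriminating = 10,
                             reversal_strength = 0.8,
                             effect_size = 1,
                             conditions_per_drug = 3,
                             noise_sd = 0.3,
                             cell_lines = c("HL60", "K562", "THP1"),
                             screen_doses = c(0.05, 0.2, 1, 2, 5),
                             screen_replicates = 2,
                             genotypes = c("wild_type", "mutant"),
                             sensitivity_fc = 4,
                             dmso_mean = 1, empty_mean = 0.05,
                             screen_noise_sd = 0.02,
                             ic50_meanlog = 0, ic50_sdlog = 0.5,
                             seed = 1) {
  cfg <- as.list(environment())
  if (!is_count(n_genes) || !is_count(n_up) || !is_count(n_down) ||
      n_up + n_down > n_genes) {
    abort_config("need counts with n_up + n_down <= n_genes")
  }
  if (!is_count(n_drugs) || n_drugs < 1) abort_config("`n_drugs` must be a positive count")
  if (is.null(names(class_sizes)) || any(names(class_sizes) == "") ||
      any(class_sizes < 1) || sum(class_sizes) > n_drugs) {
    abort_config("`class_sizes` must be a named vector of positive counts summing to <= n_drugs")
  }
  planted <- c(planted_reverser_classes, planted_mimic_classes,
               sensitive_classes, resistant_classes)
  if (!all(planted %in% names(class_sizes))) {
    abort_config("planted class names must appear in `class_sizes`")
  }
  if (!is_scalar_number(reversal_strength) ||
      reversal_strength < 0 || reversal_strength > 1) {
    abort_config("`reversal_strength` must lie in [0, 1]")
  }
  if (!is_count(conditions_per_drug) || conditions_per_drug < 1) {
    abort_config("`conditions_per_drug` must be a positive count")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_config("`noise_sd` must be >= 0")
  }
  if (!is_count(n_discriminating) || n_discriminating > n_up + n_down) {
    abort_config("`n_discriminating` must be a count <= signature size")
  }
  if (length(screen_doses) < 4L || any(screen_doses <= 0)) {
    abort_config("`screen_doses` needs at least 4 positive concentrations")
  }
  if (dmso_mean <= empty_mean) abort_config("need dmso_mean > empty_mean")
  if (length(genotypes) != 2L) abort_config("`genotypes` must name exactly two genotypes")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d genes (%d up + %d down signature), ",
                     "%d drugs in %d classes, %d condition(s)/drug\n",
                     "  reversal_strength = %.2f, noise_sd = %.2f, seed = %d\n"),
              x$n_genes, x$n_up, x$n_down, x$n_drugs, length(x$class_sizes),
              x$conditions_per_drug, x$reversal_strength, x$noise_sd, x$seed))
  invisible(x)
}

# Mouse-style source symbols and their human-style homologs; the identity-
# with-case-change map exercises the homolog-mapping stage.
synthetic_genes <- function(config) sprintf("g%04d", seq_len(config$n_genes))
synthetic_genes_human <- function(config) toupper(synthetic_genes(config))

#' Homolog map of the synthetic gene universe
#'
#' @param config A [synthetic_config()].
#' @return A tibble (`source`, `target`) mapping the mouse-style symbols to
#'   their upper-case human-style homologs.
#' @export
synthetic_homolog_map <- function(config) {
  tibble::tibble(source = synthetic_genes(config),
                 target = synthetic_genes_human(config))
}

# Deterministic drug naming and MOA assignment (no RNG involved).
build_moa <- function(config) {
  cls <- names(config$class_sizes)
  slug <- gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(cls)))
  drugs <- character(0); classes <- character(0)
  for (i in seq_along(cls)) {
    nm <- sprintf("%s%02d", sub("_$", "", slug[i]), seq_len(config$class_sizes[i]))
    drugs <- c(drugs, nm)
    classes <- c(classes, rep(cls[i], config$class_sizes[i]))
  }
  extra <- config$n_drugs - sum(config$class_sizes)
  if (extra > 0L) {
    drugs <- c(drugs, sprintf("unclassified%02d", seq_len(extra)))
    classes <- c(classes, rep(NA_character_, extra))
  }
  tibble::tibble(drug = drugs, moa_class = classes)
}

# Deterministic condition table: distinct (cell line, dose, time) tuples.
condition_table <- function(config) {
  base_dose <- c(10, 1, 0.5, 5, 0.2, 2)
  base_time <- c(24, 6)
  grid <- expand.grid(dose_uM = base_dose, time_h = base_time,
                      KEEP.OUT.ATTRS = FALSE)
  k <- config$conditions_per_drug
  if (k > nrow(grid)) {
    grid <- grid[rep(seq_len(nrow(grid)), length.out = k), , drop = FALSE]
    grid$dose_uM <- grid$dose_uM * rep(seq_len(ceiling(k / 12)),
                                       each = 12, length.out = k)
  }
  out <- grid[seq_len(k), , drop = FALSE]
  out$cell_line <- rep(config$cell_lines, length.out = k)
  tibble::tibble(cell_line = out$cell_line, dose_uM = out$dose_uM,
                 time_h = out$time_h)
}

#' Generate a synthetic differential-expression table
#'
#' Plants exactly `n_up` up-regulated and `n_down` down-regulated genes that
#' pass the default signature thresholds in both modes (log2FC >= 0.5 with
#' FDR <= 0.05; equivalently linear FC >= 1.41 or <= 0.71), while every
#' null gene receives an FDR drawn uniformly above 0.05 so that it passes
#' neither.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @param planted Optional list with `up` and `down` gene vectors to reuse
#'   planted sets across tables (e.g., two disease contrasts sharing their
#'   dysregulated genes).
#' @return A list with `table` (tibble: `gene`, `log2fc`, `fc`, `fdr`) and
#'   `truth` (list with `planted_up`, `planted_down`).
#' @export
generate_de_table <- function(config, seed = config$seed, planted = NULL) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must come from synthetic_config()")
  }
  genes <- synthetic_genes(config)
  withr::with_seed(seed, {
    if (is.null(planted)) {
      idx <- sample(config$n_genes, config$n_up + config$n_down)
      up <- genes[idx[seq_len(config$n_up)]]
      down <- genes[idx[config$n_up + seq_len(config$n_down)]]
    } else {
      up <- planted$up; down <- planted$down
      if (length(up) != config$n_up || length(down) != config$n_down) {
        abort_config("`planted` must supply `up` and `down` sets of sizes n_up and n_down")
      }
      if (length(intersect(up, down)) > 0L || !all(c(up, down) %in% genes)) {
        abort_config("`planted` sets must be disjoint subsets of the gene universe")
      }
    }
    log2fc <- rnorm(config$n_genes, 0, 0.2)
    fdr <- runif(config$n_genes, 0.05 + 1e-9, 1)
    iu <- match(up, genes); idn <- match(down, genes)
    log2fc[iu] <- 0.5 + abs(rnorm(length(iu), 0.6, 0.3))
    log2fc[idn] <- -(0.5 + abs(rnorm(length(idn), 0.6, 0.3)))
    fdr[c(iu, idn)] <- runif(length(iu) + length(idn), 0, 0.05)
    list(table = tibble::tibble(gene = genes, log2fc = log2fc,
                                fc = 2^log2fc, fdr = fdr),
         truth = list(planted_up = up, planted_down = down))
  })
}

#' Generate synthetic drug-response profiles with planted reversers
#'
#' Every drug receives `conditions_per_drug` profiles of i.i.d. normal
#' fold-change noise over the full gene universe. Drugs in a planted
#' reverser class additionally have a fraction `reversal_strength` of the
#' disease-up genes forced negative and of the disease-down genes forced
#' positive (magnitudes `|N(effect_size, noise_sd)|`); mimic classes are
#' forced with the disease sign instead. Drugs in the sensitive classes
#' reverse the `n_discriminating` planted discriminating genes the same
#' way. A tiny seeded jitter (~1e-9) makes all fold-changes distinct so
#' that rank lists are total orders.
#'
#' @param config A [synthetic_config()].
#' @param sig A [disease_signature()] over the human-style universe
#'   (`synthetic_genes_human()`); non-empty.
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with `profiles` (long tibble), `moa` (annotation tibble,
#'   unannotated drugs excluded), and `truth` (`reverser_drugs`,
#'   `mimic_drugs`, `sensitive_drugs`, `resistant_drugs`,
#'   `planted_reversal_genes`).
#' @export
generate_profiles <- function(config, sig, seed = config$seed) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must come from synthetic_config()")
  }
  if (!inherits(sig, "disease_signature") ||
      (length(sig$up) + length(sig$down)) == 0L) {
    abort_data("`sig` must be a non-empty disease_signature")
  }
  universe <- synthetic_genes_human(config)
  if (!all(c(sig$up, sig$down) %in% universe)) {
    abort_data("signature genes must lie within the synthetic gene universe")
  }
  moa_full <- build_moa(config)
  conds <- condition_table(config)
  iu <- match(sig$up, universe)
  idn <- match(sig$down, universe)
  n_force_up <- round(config$reversal_strength * length(iu))
  n_force_down <- round(config$reversal_strength * length(idn))
  withr::with_seed(seed, {
    disc <- character(0)
    if (config$n_discriminating > 0L) {
      disc <- sample(c(sig$up, sig$down), config$n_discriminating)
    }
    idisc <- match(disc, universe)
    disc_up <- disc %in% sig$up
    n_prof <- config$n_drugs * config$conditions_per_drug
    fc_mat <- matrix(0, nrow = config$n_genes, ncol = n_prof)
    col <- 0L
    for (d in seq_len(config$n_drugs)) {
      cl <- moa_full$moa_class[d]
      is_rev <- !is.na(cl) && cl %in% config$planted_reverser_classes
      is_mim <- !is.na(cl) && cl %in% config$planted_mimic_classes
      is_sens <- !is.na(cl) && cl %in% config$sensitive_classes
      for (k in seq_len(config$conditions_per_drug)) {
        col <- col + 1L
        fc <- rnorm(config$n_genes, 0, config$noise_sd)
        if (is_rev || is_mim) {
          su <- sample(iu, n_force_up)
          sd_ <- sample(idn, n_force_down)
          mag_u <- abs(rnorm(n_force_up, config$effect_size, config$noise_sd))
          mag_d <- abs(rnorm(n_force_down, config$effect_size, config$noise_sd))
          if (is_rev) {
            fc[su] <- -mag_u; fc[sd_] <- mag_d
          } else {
            fc[su] <- mag_u; fc[sd_] <- -mag_d
          }
        }
        if (is_sens && length(idisc) > 0L) {
          nf <- round(config$reversal_strength * length(idisc))
          pick <- sample(seq_along(idisc), nf)
          mag <- abs(rnorm(nf, config$effect_size, config$noise_sd))
          fc[idisc[pick]] <- ifelse(disc_up[pick], -mag, mag)
        }
        fc_mat[, col] <- fc + runif(config$n_genes, -1e-9, 1e-9)
      }
    }
    profiles <- tibble::tibble(
      drug = rep(moa_full$drug, each = config$conditions_per_drug * config$n_genes),
      cell_line = rep(rep(conds$cell_line, each = config$n_genes), config$n_drugs),
      dose_uM = rep(rep(conds$dose_uM, each = config$n_genes), config$n_drugs),
      time_h = rep(rep(conds$time_h, each = config$n_genes), config$n_drugs),
      gene = rep(universe, n_prof),
      fc = as.vector(fc_mat))
    truth <- list(
      reverser_drugs = moa_full$drug[!is.na(moa_full$moa_class) &
                                       moa_full$moa_class %in% config$planted_reverser_classes],
      mimic_drugs = moa_full$drug[!is.na(moa_full$moa_class) &
                                    moa_full$moa_class %in% config$planted_mimic_classes],
      sensitive_drugs = moa_full$drug[!is.na(moa_full$moa_class) &
                                        moa_full$moa_class %in% config$sensitive_classes],
      resistant_drugs = moa_full$drug[!is.na(moa_full$moa_class) &
                                        moa_full$moa_class %in% config$resistant_classes],
      planted_reversal_genes = disc)
    list(profiles = profiles,
         moa = moa_full[!is.na(moa_full$moa_class), , drop = FALSE],
         truth = truth)
  })
}

#' Generate a synthetic viability screen
#'
#' Simulates 96-well plates (columns 1-10 treated, column 11 DMSO, column
#' 12 empty) for both genotypes at the configured screen concentrations.
#' Each drug gets a log-normal wild-type IC50 and a Hill slope; drugs of
#' the sensitive classes have their mutant IC50 divided by
#' `sensitivity_fc`, resistant classes multiplied by it. Well signals are
#' `empty_mean + viability * (dmso_mean - empty_mean) + noise` with
#' viability from the 4PL curve ([four_pl()], top 1, bottom 0).
#'
#' @param config A [synthetic_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with `plates` (well-long tibble: `plate`, `well`, `role`,
#'   `drug`, `dose_uM`, `genotype`, `signal`) and `truth` (`true_ic50`
#'   tibble with `drug`, `genotype`, `ic50`, `hill`; `sensitive_drugs`;
#'   `resistant_drugs`).
#' @export
generate_screen <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must come from synthetic_config()")
  }
  moa_full <- build_moa(config)
  drugs <- moa_full$drug
  sens <- !is.na(moa_full$moa_class) &
    moa_full$moa_class %in% config$sensitive_classes
  resist <- !is.na(moa_full$moa_class) &
    moa_full$moa_class %in% config$resistant_classes
  n_dose <- length(config$screen_doses)
  per_plate <- 80L %/% n_dose           # drugs per 96-well plate
  withr::with_seed(seed, {
    base_ic50 <- exp(rnorm(length(drugs), config$ic50_meanlog, config$ic50_sdlog))
    hill <- runif(length(drugs), 0.8, 1.6)
    ic50 <- tibble::tibble(
      drug = rep(drugs, 2L),
      genotype = rep(config$genotypes, each = length(drugs)),
      ic50 = c(base_ic50,
               base_ic50 * ifelse(sens, 1 / config$sensitivity_fc,
                                  ifelse(resist, config$sensitivity_fc, 1))),
      hill = rep(hill, 2L))
    rows <- LETTERS[1:8]
    wells <- vector("list", 0L)
    for (g in config$genotypes) {
      chunks <- split(seq_along(drugs),
                      (seq_along(drugs) - 1L) %/% per_plate)
      for (r in seq_len(config$screen_replicates)) {
        for (ci in seq_along(chunks)) {
          pid <- sprintf("%s_rep%d_p%02d", g, r, ci)
          di <- chunks[[ci]]
          slot <- 0L
          tw <- vector("list", 0L)
          for (d in di) {
            ic <- ic50$ic50[ic50$drug == drugs[d] & ic50$genotype == g]
            for (j in seq_len(n_dose)) {
              row <- slot %/% 10L + 1L
              coln <- slot %% 10L + 1L
              slot <- slot + 1L
              v <- four_pl(config$screen_doses[j], top = 1, bottom = 0,
                           ic50 = ic, hill = hill[d])
              tw[[length(tw) + 1L]] <- tibble::tibble(
                plate = pid, well = sprintf("%s%02d", rows[row], coln),
                role = "treated", drug = drugs[d],
                dose_uM = config$screen_doses[j], genotype = g,
                viability = v)
            }
          }
          ctrl <- tibble::tibble(
            plate = pid,
            well = c(sprintf("%s11", rows), sprintf("%s12", rows)),
            role = rep(c("dmso", "empty"), each = 8L),
            drug = NA_character_, dose_uM = NA_real_, genotype = g,
            viability = rep(c(1, 0), each = 8L))
          wells[[length(wells) + 1L]] <- dplyr::bind_rows(dplyr::bind_rows(tw), ctrl)
        }
      }
    }
    plates <- dplyr::bind_rows(wells)
    plates$signal <- config$empty_mean +
      plates$viability * (config$dmso_mean - config$empty_mean) +
      rnorm(nrow(plates), 0, config$screen_noise_sd)
    plates$viability <- NULL
    truth <- list(true_ic50 = ic50,
                  sensitive_drugs = drugs[sens],
                  resistant_drugs = drugs[resist])
    list(plates = plates, truth = truth)
  })
}
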