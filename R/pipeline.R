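# Orchestration: reproducible end-to-end runs over files on disk. All
# artifacts are plain TSV/JSON so runs are diff-able; every run emits a
# manifest with row counts, collected warnings and timing.

sub_seed <- function(seed, k) (as.integer(seed) %% 2000000000L) + k

write_manifest <- function(path, stage, counts, warnings, started, config = NULL) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("revsig")),
    config = config,
    row_counts = counts,
    warnings = warnings,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = round(as.numeric(difftime(Sys.time(), started, units = "secs")), 3))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

collect_warnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates two differential-expression tables for the same planted
#' disease genes (one filtered downstream in log2FC mode, one in linear FC
#' mode — two disease contrasts), the drug-response profiles, MOA
#' annotation, homolog map, the viability screen, and a ground-truth JSON.
#' Runs are idempotent for a fixed config and seed.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed (defaults to `config$seed`); stage seeds are
#'   derived from it.
#' @return Invisibly, a list with the written `paths` and the combined
#'   `truth`.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir,
                         seed = config$seed) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must come from synthetic_config()")
  }
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    de1 <- generate_de_table(config, sub_seed(seed, 0L))
    de2 <- generate_de_table(config, sub_seed(seed, 1L),
                             planted = list(up = de1$truth$planted_up,
                                            down = de1$truth$planted_down))
    sig_src <- build_signature(de1$table, signature_thresholds(),
                               name = "mutant")
    hmap <- synthetic_homolog_map(config)
    sig <- map_homologs(sig_src, hmap)
    prof <- generate_profiles(config, sig, sub_seed(seed, 2L))
    scr <- generate_screen(config, sub_seed(seed, 3L))
    list(de1 = de1, de2 = de2, prof = prof, scr = scr, hmap = hmap)
  })
  v <- res$value
  paths <- list(
    de_mutant = file.path(out_dir, "de_mutant.tsv"),
    de_knockdown = file.path(out_dir, "de_knockdown.tsv"),
    profiles = file.path(out_dir, "profiles.tsv"),
    moa = file.path(out_dir, "moa.tsv"),
    homolog_map = file.path(out_dir, "homolog_map.tsv"),
    plates = file.path(out_dir, "plates.tsv"),
    truth = file.path(out_dir, "truth.json"))
  readr::write_tsv(v$de1$table, paths$de_mutant, progress = FALSE)
  readr::write_tsv(v$de2$table, paths$de_knockdown, progress = FALSE)
  readr::write_tsv(v$prof$profiles, paths$profiles, progress = FALSE)
  readr::write_tsv(v$prof$moa, paths$moa, progress = FALSE)
  readr::write_tsv(v$hmap, paths$homolog_map, progress = FALSE)
  readr::write_tsv(v$scr$plates, paths$plates, progress = FALSE)
  truth <- c(v$de1$truth, v$prof$truth,
             v$scr$truth[c("true_ic50", "resistant_drugs")])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  write_manifest(file.path(out_dir, "manifest.json"), "simulate",
                 counts = list(de_rows = nrow(v$de1$table),
                               profile_rows = nrow(v$prof$profiles),
                               plate_wells = nrow(v$scr$plates)),
                 warnings = res$warnings, started = started,
                 config = unclass(config))
  invisible(list(paths = paths, truth = truth))
}

#' Run the prediction arm: signatures, RGES/sRGES, class enrichment
#'
#' Reads a dataset directory (as written by [run_simulate()], or any
#' directory with the same file layout), builds both disease signatures
#' (the first in log2FC mode, the second in linear FC mode), maps them onto
#' the drug-profile universe, scores every profile, summarizes sRGES per
#' drug, runs MOA class enrichment against each signature, and selects
#' candidate classes passing in both.
#'
#' @param input_dir Directory with `de_mutant.tsv`, `de_knockdown.tsv`,
#'   `profiles.tsv`, `moa.tsv`, and optionally `homolog_map.tsv`.
#' @param out_dir Output directory.
#' @param srges_strategy Summarization strategy for [summarize_srges()].
#' @param cell_lines Optional cell-line whitelist for [filter_profiles()].
#' @param es_max,p_max Candidate-selection cutoffs ([select_candidates()]).
#' @param min_size Minimum MOA class size ([class_enrichment()]).
#' @param thresholds1,thresholds2 [signature_thresholds()] for the two DE
#'   tables.
#' @return Invisibly, a list with `signatures`, `srges` (per signature),
#'   `enrichment` (per signature), and `candidates`.
#' @export
run_predict <- function(input_dir, out_dir,
                        srges_strategy = c("mean", "condition_weighted"),
                        cell_lines = NULL, es_max = 0, p_max = 0.05,
                        min_size = 3,
                        thresholds1 = signature_thresholds(),
                        thresholds2 = signature_thresholds(mode = "fc")) {
  srges_strategy <- match.arg(srges_strategy)
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    de1 <- read_de_table(file.path(input_dir, "de_mutant.tsv"))
    de2 <- read_de_table(file.path(input_dir, "de_knockdown.tsv"))
    profiles <- read_profiles(file.path(input_dir, "profiles.tsv"))
    moa <- read_moa(file.path(input_dir, "moa.tsv"))
    if (!is.null(cell_lines)) profiles <- filter_profiles(profiles, cell_lines)
    sigs <- list(
      mutant = build_signature(de1, thresholds1, name = "mutant"),
      knockdown = build_signature(de2, thresholds2, name = "knockdown"))
    hmap_path <- file.path(input_dir, "homolog_map.tsv")
    if (file.exists(hmap_path)) {
      hmap <- readr::read_tsv(hmap_path, show_col_types = FALSE,
                              progress = FALSE)
      sigs <- lapply(sigs, map_homologs, map = hmap,
                     fallback_uppercase = TRUE)
    }
    per_sig <- lapply(sigs, function(sg) {
      rg <- rges_table(profiles, sg)
      sr <- summarize_srges(rg, strategy = srges_strategy)
      en <- class_enrichment(sr, moa, min_size = min_size)
      list(rges = rg, srges = sr, enrichment = en)
    })
    cand <- select_candidates(per_sig$mutant$enrichment,
                              per_sig$knockdown$enrichment,
                              es_max = es_max, p_max = p_max)
    list(sigs = sigs, per_sig = per_sig, cand = cand)
  })
  v <- res$value
  for (nm in names(v$sigs)) {
    write_signature(v$sigs[[nm]], file.path(out_dir, sprintf("signature_%s.tsv", nm)))
    readr::write_tsv(v$per_sig[[nm]]$rges,
                     file.path(out_dir, sprintf("rges_%s.tsv", nm)),
                     progress = FALSE)
    readr::write_tsv(v$per_sig[[nm]]$srges,
                     file.path(out_dir, sprintf("srges_%s.tsv", nm)),
                     progress = FALSE)
    readr::write_tsv(v$per_sig[[nm]]$enrichment,
                     file.path(out_dir, sprintf("enrichment_%s.tsv", nm)),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(selection = list(es_max = es_max, p_max = p_max),
         candidates = v$cand,
         enrichment = lapply(v$per_sig, function(x) x$enrichment)),
    file.path(out_dir, "candidates.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_manifest(file.path(out_dir, "manifest.json"), "predict",
                 counts = list(
                   signature_mutant = length(v$sigs$mutant$up) + length(v$sigs$mutant$down),
                   signature_knockdown = length(v$sigs$knockdown$up) + length(v$sigs$knockdown$down),
                   profiles_scored = nrow(v$per_sig$mutant$rges),
                   drugs = nrow(v$per_sig$mutant$srges),
                   candidates = nrow(v$cand)),
                 warnings = res$warnings, started = started)
  invisible(list(signatures = v$sigs,
                 srges = lapply(v$per_sig, function(x) x$srges),
                 enrichment = lapply(v$per_sig, function(x) x$enrichment),
                 candidates = v$cand))
}

#' Run the phenotype arm: screen response, correlation, reversal genes
#'
#' Normalizes the plate screen, derives per-drug response fold-changes
#' (mutant vs wild-type) via the two-tier IC50/viability rule, correlates
#' them with predicted reversal (sRGES from a [run_predict()] output), and
#' identifies sensitivity-discriminating reversal genes by comparing
#' profiles of sensitive versus insensitive MOA classes. Sensitive classes
#' are derived from the phenotype concordance classes (a class is sensitive
#' when at least half of its drugs fall in class I or II) unless explicit
#' class lists are supplied.
#'
#' @param input_dir Dataset directory (needs `plates.tsv`, `profiles.tsv`,
#'   `moa.tsv`, `de_mutant.tsv`, optionally `homolog_map.tsv`).
#' @param predict_dir Directory with `srges_mutant.tsv` from
#'   [run_predict()].
#' @param out_dir Output directory.
#' @param sens_fc_max,srges_neg_max Concordance-class thresholds
#'   ([correlate_prediction()]).
#' @param fdr_max,min_fraction Reversal-gene selection thresholds
#'   ([sensitive_vs_insensitive()]).
#' @param exclude_classes MOA classes excluded from the reversal-gene
#'   comparison (e.g., broad over-reversers). Default none.
#' @param sensitive_classes,insensitive_classes Optional explicit grouping
#'   override.
#' @param genotypes `c(mutant, wild_type)` genotype labels in the plate
#'   table.
#' @return Invisibly, a list with `phenotypes`, `correlation`,
#'   `sensitive_classes`, `insensitive_classes`, and `reversal_genes`
#'   (`NULL` when the stage was skipped).
#' @export
run_correlate <- function(input_dir, predict_dir, out_dir,
                          sens_fc_max = 0.67, srges_neg_max = 0,
                          fdr_max = 0.25, min_fraction = 0.6,
                          exclude_classes = character(0),
                          sensitive_classes = NULL,
                          insensitive_classes = NULL,
                          genotypes = c("mutant", "wild_type")) {
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    plates <- read_plates(file.path(input_dir, "plates.tsv"))
    viab <- normalize_plates(plates)
    phen <- screen_phenotypes(viab, genotypes = genotypes)
    srges <- readr::read_tsv(file.path(predict_dir, "srges_mutant.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    corr <- correlate_prediction(phen, srges, sens_fc_max = sens_fc_max,
                                 srges_neg_max = srges_neg_max)
    moa <- read_moa(file.path(input_dir, "moa.tsv"))
    profiles <- read_profiles(file.path(input_dir, "profiles.tsv"))
    de1 <- read_de_table(file.path(input_dir, "de_mutant.tsv"))
    sig <- build_signature(de1, signature_thresholds(), name = "mutant")
    hmap_path <- file.path(input_dir, "homolog_map.tsv")
    if (file.exists(hmap_path)) {
      hmap <- readr::read_tsv(hmap_path, show_col_types = FALSE,
                              progress = FALSE)
      sig <- map_homologs(sig, hmap, fallback_uppercase = TRUE)
    }
    if (is.null(sensitive_classes) || is.null(insensitive_classes)) {
      cls_tab <- dplyr::inner_join(corr$records, moa, by = "drug") |>
        dplyr::group_by(.data$moa_class) |>
        dplyr::summarise(frac_sens = mean(.data$cls %in% c("I", "II")),
                         .groups = "drop")
      auto_sens <- cls_tab$moa_class[cls_tab$frac_sens >= 0.5]
      auto_insens <- cls_tab$moa_class[cls_tab$frac_sens < 0.5]
      if (is.null(sensitive_classes)) sensitive_classes <- auto_sens
      if (is.null(insensitive_classes)) insensitive_classes <- auto_insens
    }
    sensitive_classes <- setdiff(sensitive_classes, exclude_classes)
    insensitive_classes <- setdiff(insensitive_classes,
                                   c(exclude_classes, sensitive_classes))
    rg <- NULL
    if (length(sensitive_classes) == 0L || length(insensitive_classes) == 0L) {
      warning("no sensitive (or no insensitive) drug class found; reversal-gene stage skipped",
              call. = FALSE)
    } else {
      sens_drugs <- moa$drug[moa$moa_class %in% sensitive_classes]
      insens_drugs <- moa$drug[moa$moa_class %in% insensitive_classes]
      rg <- sensitive_vs_insensitive(
        profiles[profiles$drug %in% sens_drugs, , drop = FALSE],
        profiles[profiles$drug %in% insens_drugs, , drop = FALSE],
        sig, fdr_max = fdr_max, min_fraction = min_fraction)
    }
    list(phen = phen, corr = corr, rg = rg, moa = moa, profiles = profiles,
         sensitive_classes = sensitive_classes,
         insensitive_classes = insensitive_classes)
  })
  v <- res$value
  readr::write_tsv(v$phen, file.path(out_dir, "phenotypes.tsv"),
                   progress = FALSE)
  scatter <- dplyr::transmute(v$corr$records, drug = .data$drug,
                              srges = .data$srges,
                              log2_response_fc = log2(.data$response_fc),
                              cls = .data$cls)
  readr::write_tsv(scatter, file.path(out_dir, "phenotype_scatter.tsv"),
                   progress = FALSE)
  if (!is.null(v$rg)) {
    readr::write_tsv(v$rg, file.path(out_dir, "reversal_genes.tsv"),
                     progress = FALSE)
    sel <- v$rg$gene[v$rg$selected]
    if (length(sel) > 0L) {
      keep <- v$moa$moa_class %in% c(v$sensitive_classes, v$insensitive_classes)
      mat <- class_mean_fc_matrix(v$profiles, v$moa[keep, , drop = FALSE], sel)
      readr::write_tsv(
        dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                         tibble::as_tibble(mat)),
        file.path(out_dir, "reversal_matrix.tsv"), progress = FALSE)
    }
  }
  write_manifest(file.path(out_dir, "manifest.json"), "correlate",
                 counts = list(drugs_phenotyped = nrow(v$phen),
                               drugs_correlated = nrow(v$corr$records),
                               reversal_genes_tested =
                                 if (is.null(v$rg)) 0L else sum(v$rg$tested),
                               reversal_genes_selected =
                                 if (is.null(v$rg)) 0L else sum(v$rg$selected)),
                 warnings = res$warnings, started = started)
  invisible(list(phenotypes = v$phen, correlation = v$corr,
                 sensitive_classes = v$sensitive_classes,
                 insensitive_classes = v$insensitive_classes,
                 reversal_genes = v$rg))
}
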