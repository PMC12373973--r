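#' Mechanism-of-action class enrichment on the sRGES ranking
#'
#' Groups drugs by mechanism-of-action (MOA) class and asks, per class,
#' whether its members concentrate at the reversal (low-sRGES) end of the
#' drug ranking. Drugs are ranked by sRGES in descending order, so the
#' strongest predicted reversers sit at the bottom; the unweighted
#' Kolmogorov-Smirnov statistic [ks_es()] of the member positions is then
#' negative when the class is enriched at the reversal end. Significance is
#' assessed with a one-tailed Welch t-test of member versus non-member
#' sRGES (alternative: member mean lower).
#'
#' Classes smaller than `min_size`, and a class covering every ranked drug
#' (no complement to compare against), are reported untested with a reason.
#' When the t-test degenerates (e.g., zero variance in both groups) the
#' p-value falls back to 1.
#'
#' @param srges Tibble with columns `drug` and `srges` (one row per drug),
#'   e.g. from [summarize_srges()]. Must cover every annotated drug.
#' @param moa Tibble with columns `drug` and `moa_class` (each drug in at
#'   most one class).
#' @param min_size Minimum class size to test. Default 3.
#' @return A tibble with one row per class: `moa_class`, `n_members`,
#'   `mean_srges`, `es`, `p`, `fdr` (Benjamini-Hochberg across tested
#'   classes, provided as a convenience column), `tested`, `reason`.
#' @export
class_enrichment <- function(srges, moa, min_size = 3) {
  need_cols(srges, c("drug", "srges"), "sRGES table")
  need_cols(moa, c("drug", "moa_class"), "MOA table")
  if (anyDuplicated(srges$drug) > 0L) abort_data("sRGES table must have one row per drug")
  if (anyDuplicated(moa$drug) > 0L) abort_data("each drug may belong to at most one MOA class")
  moa <- moa[moa$drug %in% srges$drug, , drop = FALSE]
  if (nrow(moa) == 0L) abort_data("no annotated drug is present in the sRGES table")
  classes <- sort(unique(moa$moa_class))
  if (length(classes) < 2L) {
    abort_data("need at least 2 MOA classes for enrichment")
  }
  # descending sRGES: strongest reversers occupy the last positions
  ord <- order_radix(-srges$srges, srges$drug)
  ranked_drugs <- srges$drug[ord]
  n <- length(ranked_drugs)
  rows <- lapply(classes, function(cl) {
    members <- moa$drug[moa$moa_class == cl]
    m_srges <- srges$srges[match(members, srges$drug)]
    base <- tibble::tibble(moa_class = cl, n_members = length(members),
                           mean_srges = mean(m_srges))
    if (length(members) < min_size) {
      return(dplyr::mutate(base, es = NA_real_, p = NA_real_,
                           tested = FALSE, reason = "below_min_size"))
    }
    if (length(members) >= n) {
      return(dplyr::mutate(base, es = NA_real_, p = NA_real_,
                           tested = FALSE, reason = "no_complement"))
    }
    pos <- sort(match(members, ranked_drugs))
    es <- ks_es(pos, n)$es
    others <- srges$srges[!(srges$drug %in% members)]
    p <- tryCatch(
      t.test(m_srges, others, alternative = "less")$p.value,
      error = function(e) 1
    )
    dplyr::mutate(base, es = es, p = p, tested = TRUE, reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  dplyr::arrange(out, .data$p, .data$moa_class)
}

#' Select candidate drug classes across two disease signatures
#'
#' A class is a candidate when it is significantly enriched at the reversal
#' end (`es < es_max` and `p <= p_max`) against *both* disease signatures —
#' the overlap rule that guards against signature-specific artifacts.
#'
#' @param results_sig1,results_sig2 Enrichment tables from
#'   [class_enrichment()] for the two signatures (shared class vocabulary).
#' @param es_max Enrichment-score cutoff (default 0: must be negative).
#' @param p_max One-tailed p-value cutoff (default 0.05).
#' @return A tibble of selected classes with both signatures' statistics
#'   (`es_1`, `p_1`, `es_2`, `p_2`, `mean_p`), sorted by `mean_p`. Empty
#'   (zero rows) when no class passes in both.
#' @export
select_candidates <- function(results_sig1, results_sig2,
                              es_max = 0, p_max = 0.05) {
  need_cols(results_sig1, c("moa_class", "es", "p"), "enrichment table 1")
  need_cols(results_sig2, c("moa_class", "es", "p"), "enrichment table 2")
  joined <- dplyr::inner_join(
    dplyr::select(results_sig1, "moa_class", es_1 = "es", p_1 = "p"),
    dplyr::select(results_sig2, "moa_class", es_2 = "es", p_2 = "p"),
    by = "moa_class")
  pass <- !is.na(joined$es_1) & !is.na(joined$es_2) &
    joined$es_1 < es_max & joined$p_1 <= p_max &
    joined$es_2 < es_max & joined$p_2 <= p_max
  out <- joined[pass, , drop = FALSE]
  out$mean_p <- (out$p_1 + out$p_2) / 2
  dplyr::arrange(out, .data$mean_p, .data$moa_class)
}

#' Read a drug-to-MOA annotation table from TSV
#'
#' @param path TSV with columns `drug` and `moa_class`.
#' @return A tibble.
#' @export
read_moa <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(tab, c("drug", "moa_class"), sprintf("MOA table '%s'", path))
  if (nrow(tab) == 0L) abort_data(sprintf("MOA table '%s' is empty", path))
  tab
}
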