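#' Reversal gene expression score (RGES) of one drug profile
#'
#' Scores how strongly a single drug-response profile reverses a disease
#' signature. The profile's genes are ranked by drug-induced fold-change
#' (rank 1 = most up-regulated, ties broken by gene symbol), the positions
#' of the disease up- and down-sets are located in that ranking, and each
#' set receives the Kolmogorov-Smirnov enrichment statistic [ks_es()]. The
#' score is
#' \deqn{RGES = es_{up} - es_{down} \in [-2, 2].}
#' A drug that pushes disease-up genes to the bottom of its ranking and
#' disease-down genes to the top (a reverser) gets a strongly negative RGES;
#' a drug mimicking the disease gets a positive one.
#'
#' Signature genes absent from the profile universe are dropped for that
#' profile. If either intersected set is empty the profile cannot be scored
#' and a skip record (`skipped = TRUE` with a reason code) is returned
#' rather than a score of zero.
#'
#' @param fc Named numeric vector of per-gene signed fold-changes for one
#'   profile (names are gene symbols; at least 2 genes).
#' @param sig A [disease_signature()].
#' @return A list of class `"rges_record"` with `es_up`, `es_down`, `rges`,
#'   effective set sizes `t_up`, `t_down`, universe size `n`, and `skipped`
#'   (with `reason` when `TRUE`).
#' @examples
#' fc <- setNames(c(3, 2, -1, -2), c("D1", "D2", "U1", "U2"))
#' rges_score(fc, disease_signature(up = c("U1", "U2"), down = c("D1", "D2")))
#' @export
rges_score <- function(fc, sig) {
  if (!inherits(sig, "disease_signature")) {
    abort_config("`sig` must be a disease_signature")
  }
  genes <- names(fc)
  if (is.null(genes) || length(fc) < 2L) {
    abort_data("`fc` must be a named vector with at least 2 genes")
  }
  n <- length(fc)
  ranked <- genes[order_radix(-fc, genes)]
  pos_up <- sort(match(sig$up, ranked))
  pos_up <- pos_up[!is.na(pos_up)]
  pos_down <- sort(match(sig$down, ranked))
  pos_down <- pos_down[!is.na(pos_down)]
  skip <- function(reason) {
    structure(list(es_up = NA_real_, es_down = NA_real_, rges = NA_real_,
                   t_up = length(pos_up), t_down = length(pos_down), n = n,
                   skipped = TRUE, reason = reason), class = "rges_record")
  }
  if (length(pos_up) == 0L) return(skip("empty_up_set"))
  if (length(pos_down) == 0L) return(skip("empty_down_set"))
  es_up <- ks_es(pos_up, n)$es
  es_down <- ks_es(pos_down, n)$es
  structure(list(es_up = es_up, es_down = es_down, rges = es_up - es_down,
                 t_up = length(pos_up), t_down = length(pos_down), n = n,
                 skipped = FALSE, reason = NA_character_),
            class = "rges_record")
}

#' @export
print.rges_record <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("<rges_record> skipped (%s)\n", x$reason))
  } else {
    cat(sprintf("<rges_record> rges = %.4f (es_up = %.4f, es_down = %.4f; t_up = %d, t_down = %d, n = %d)\n",
                x$rges, x$es_up, x$es_down, x$t_up, x$t_down, x$n))
  }
  invisible(x)
}

#' RGES for every profile in a long profile table
#'
#' Applies [rges_score()] to each (drug, cell_line, dose, time) profile.
#' Profiles whose intersected up- or down-set is empty are dropped with a
#' warning summarizing the reason codes.
#'
#' @param profiles Long-form profile tibble (`drug`, `cell_line`, `dose_uM`,
#'   `time_h`, `gene`, `fc`).
#' @param sig A [disease_signature()].
#' @return A tibble with one row per scored profile: condition columns plus
#'   `n`, `t_up`, `t_down`, `es_up`, `es_down`, `rges`.
#' @export
rges_table <- function(profiles, sig) {
  need_cols(profiles, c("drug", "cell_line", "dose_uM", "time_h", "gene", "fc"),
            "profile table")
  idx <- split(seq_len(nrow(profiles)), profile_id(profiles))
  rows <- vector("list", length(idx))
  skipped <- character(0)
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    rec <- rges_score(setNames(profiles$fc[i], profiles$gene[i]), sig)
    if (rec$skipped) {
      skipped <- c(skipped, rec$reason)
      next
    }
    rows[[k]] <- tibble::tibble(
      drug = profiles$drug[i[1L]], cell_line = profiles$cell_line[i[1L]],
      dose_uM = profiles$dose_uM[i[1L]], time_h = profiles$time_h[i[1L]],
      n = rec$n, t_up = rec$t_up, t_down = rec$t_down,
      es_up = rec$es_up, es_down = rec$es_down, rges = rec$rges)
  }
  if (length(skipped) > 0L) {
    warning(sprintf("skipped %d profile(s): %s", length(skipped),
                    paste(names(table(skipped)), table(skipped),
                          sep = " x ", collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort_data("no profile could be scored against the signature")
  dplyr::arrange(out, .data$drug, .data$cell_line, .data$dose_uM, .data$time_h)
}

#' Summarize per-profile RGES into one sRGES per drug
#'
#' Collapses the per-condition reversal scores of each drug into a single
#' summarized RGES (sRGES). Two strategies are provided:
#'
#' * `"mean"` — arithmetic mean of the drug's per-profile RGES.
#' * `"condition_weighted"` — profiles are first adjusted toward a reference
#'   condition (default 10 uM, 24 h): conditions are stratified by
#'   (dose, time); for each stratum the median offset of drug-level mean
#'   RGES relative to the reference stratum, estimated from drugs measured
#'   in both, is subtracted; adjusted scores are then averaged per drug.
#'   Strata with no drug in common with the reference get offset 0.
#'
#' @param rges A tibble from [rges_table()].
#' @param strategy `"mean"` or `"condition_weighted"`.
#' @param ref_dose,ref_time Reference condition for `"condition_weighted"`
#'   (uM, hours). The stratum closest to it in log-dose/log-time distance is
#'   used as reference.
#' @return A tibble (`drug`, `srges`, `n_profiles`, `strategy`) sorted
#'   ascending by `srges` (strongest predicted reversers first).
#' @export
summarize_srges <- function(rges, strategy = c("mean", "condition_weighted"),
                            ref_dose = 10, ref_time = 24) {
  strategy <- match.arg(strategy)
  need_cols(rges, c("drug", "dose_uM", "time_h", "rges"), "RGES table")
  if (nrow(rges) == 0L) abort_data("RGES table is empty")
  if (strategy == "condition_weighted") {
    strata <- dplyr::distinct(rges, .data$dose_uM, .data$time_h)
    d <- abs(log10(strata$dose_uM / ref_dose)) + abs(log2(strata$time_h / ref_time))
    ref <- strata[order(d, strata$dose_uM, strata$time_h)[1L], ]
    drug_stratum <- rges |>
      dplyr::group_by(.data$drug, .data$dose_uM, .data$time_h) |>
      dplyr::summarise(m = mean(.data$rges), .groups = "drop")
    ref_means <- drug_stratum[drug_stratum$dose_uM == ref$dose_uM &
                                drug_stratum$time_h == ref$time_h, ]
    offsets <- vapply(seq_len(nrow(strata)), function(i) {
      s <- drug_stratum[drug_stratum$dose_uM == strata$dose_uM[i] &
                          drug_stratum$time_h == strata$time_h[i], ]
      common <- intersect(s$drug, ref_means$drug)
      if (length(common) == 0L) return(0)
      median(s$m[match(common, s$drug)] - ref_means$m[match(common, ref_means$drug)])
    }, numeric(1))
    key <- paste(rges$dose_uM, rges$time_h)
    skey <- paste(strata$dose_uM, strata$time_h)
    rges$rges <- rges$rges - offsets[match(key, skey)]
  }
  out <- rges |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(srges = mean(.data$rges), n_profiles = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(strategy = strategy) |>
    dplyr::arrange(.data$srges, .data$drug)
  out
}

#' Mean per-gene fold-change across a drug's profiles
#'
#' For ranking and visualization of a drug's overall transcriptional effect,
#' the per-gene fold-changes are averaged over all of the drug's treatment
#' conditions; a gene contributes only from the profiles that contain it.
#'
#' @param profiles Long-form profile tibble (one or several drugs).
#' @return A tibble (`drug`, `gene`, `mean_fc`, `n_profiles`).
#' @export
mean_gene_fc <- function(profiles) {
  need_cols(profiles, c("drug", "gene", "fc"), "profile table")
  if (nrow(profiles) == 0L) abort_data("profile table is empty")
  profiles |>
    dplyr::group_by(.data$drug, .data$gene) |>
    dplyr::summarise(mean_fc = mean(.data$fc), n_profiles = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$drug, .data$gene)
}
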