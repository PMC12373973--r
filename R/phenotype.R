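# Phenotype layer: plate normalization, four-parameter logistic (4PL)
# dose-response fitting, per-drug sensitivity fold-changes between
# genotypes, and the correlation of phenotypic response with predicted
# transcriptional reversal (sRGES).

#' Normalize raw plate signals to viability
#'
#' Within-plate normalization against DMSO (vehicle) and empty wells:
#' \deqn{viability = \frac{signal - \bar{s}_{empty}}{\bar{s}_{DMSO} - \bar{s}_{empty}}}
#' computed per plate, so DMSO wells average 1 and empty wells 0. The
#' transformation is invariant to per-plate affine rescaling of the raw
#' signals.
#'
#' @param plates Tibble of wells with columns `plate`, `well`, `role`
#'   (`"treated"`, `"dmso"`, or `"empty"`), `drug`, `dose_uM`, `genotype`,
#'   `signal`.
#' @return The input with a `viability` column added.
#' @export
normalize_plates <- function(plates) {
  need_cols(plates, c("plate", "well", "role", "signal"), "plate table")
  bad_role <- setdiff(unique(plates$role), c("treated", "dmso", "empty"))
  if (length(bad_role) > 0L) {
    abort_data(sprintf("unknown well role(s): %s", paste(bad_role, collapse = ", ")))
  }
  out <- vector("list", 0L)
  for (pl in unique(plates$plate)) {
    w <- plates[plates$plate == pl, , drop = FALSE]
    dmso <- w$signal[w$role == "dmso"]
    empty <- w$signal[w$role == "empty"]
    if (length(dmso) == 0L || length(empty) == 0L) {
      abort_data(sprintf("plate '%s' lacks DMSO and/or empty wells", pl))
    }
    dm <- mean(dmso); em <- mean(empty)
    if (dm <= em) {
      abort_data(sprintf("plate '%s' failed: DMSO mean (%.3g) <= empty mean (%.3g)",
                         pl, dm, em))
    }
    w$viability <- (w$signal - em) / (dm - em)
    out[[length(out) + 1L]] <- w
  }
  dplyr::bind_rows(out)
}

#' Four-parameter logistic dose-response curve
#'
#' \deqn{v(d) = bottom + \frac{top - bottom}{1 + (d / IC_{50})^{hill}}}
#'
#' @param dose Doses (same unit as `ic50`).
#' @param top,bottom Upper/lower viability asymptotes.
#' @param ic50 Half-maximal inhibitory concentration (> 0).
#' @param hill Hill slope (> 0 for a decreasing curve).
#' @return Predicted viabilities.
#' @export
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model on log-dose via Levenberg-Marquardt
#' (box-bounded), with a multi-start grid over IC50 (log-spaced across the
#' tested range) and Hill slope to avoid local minima. A flat response
#' (per-dose mean range below `flat_tol`) or a fit with `bottom > top`
#' (non-inhibitory) yields an honest non-converged result — such drugs are
#' handled downstream by the screening viability-ratio path instead of an
#' IC50 ratio.
#'
#' @param dose Positive doses; at least 4 distinct values (replicates
#'   allowed: pass repeated doses with their viabilities).
#' @param viability Observed viabilities, same length as `dose`.
#' @param flat_tol Minimum per-dose mean range for a fit to be attempted.
#'   Default 0.1.
#' @return A list of class `"dose_response_fit"`: `top`, `bottom`, `hill`,
#'   `ic50`, `converged`, `reason` (when not converged), `rss`,
#'   `extrapolated` (`TRUE` when the fitted IC50 falls outside 0.1x-10x the
#'   tested dose range), `n`.
#' @export
fit_dose_response <- function(dose, viability, flat_tol = 0.1) {
  if (length(dose) != length(viability)) {
    abort_data("`dose` and `viability` must have the same length")
  }
  keep <- !is.na(dose) & !is.na(viability)
  dose <- dose[keep]; viability <- viability[keep]
  if (any(dose <= 0)) abort_data("doses must be positive")
  if (length(unique(dose)) < 4L) {
    abort_data("need at least 4 distinct doses for a 4PL fit")
  }
  no_fit <- function(reason) {
    structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                   ic50 = NA_real_, converged = FALSE, reason = reason,
                   rss = NA_real_, extrapolated = NA, n = length(dose)),
              class = "dose_response_fit")
  }
  mv <- tapply(viability, dose, mean)
  if (diff(range(mv)) < flat_tol) return(no_fit("flat_response"))
  dat <- data.frame(dose = dose, v = viability)
  lo <- c(top = -1, bottom = -1, lic50 = log(min(dose)) - log(1000),
          hill = 0.01)
  hi <- c(top = 3, bottom = 3, lic50 = log(max(dose)) + log(1000), hill = 20)
  starts <- expand.grid(
    lic50 = seq(log(min(dose)), log(max(dose)), length.out = 5L),
    hill = c(0.5, 1, 2, 4))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (dose / exp(lic50))^hill),
        data = dat,
        start = list(top = max(mv), bottom = min(mv),
                     lic50 = starts$lic50[s], hill = starts$hill[s]),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(no_fit("no_convergence"))
  cf <- coef(best$fit)
  if (cf[["bottom"]] > cf[["top"]]) return(no_fit("non_inhibitory"))
  ic50 <- exp(cf[["lic50"]])
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]],
                 hill = cf[["hill"]], ic50 = ic50, converged = TRUE,
                 reason = NA_character_, rss = best$rss,
                 extrapolated = ic50 < 0.1 * min(dose) || ic50 > 10 * max(dose),
                 n = length(dose)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<dose_response_fit> ic50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g, rss = %.3g%s\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss,
                if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  } else {
    cat(sprintf("<dose_response_fit> not converged (%s)\n", x$reason))
  }
  invisible(x)
}

#' Per-drug phenotypic response fold-change between genotypes
#'
#' Two-tier rule: when converged IC50 fits exist for both genotypes the
#' response is the IC50 ratio (mutant / wild-type); otherwise it is the mean
#' over tested concentrations of the per-concentration viability ratio
#' (mutant / wild-type) from the screen. A value below 1 means the mutant
#' genotype is more sensitive to the drug.
#'
#' @param fit_mut,fit_wt `"dose_response_fit"` objects (or `NULL`).
#' @param viability_ratio Per-concentration viability ratios
#'   (mutant / wild-type), used when either fit is unavailable.
#' @return A list with `response_fc` and `basis` (`"ic50_ratio"` or
#'   `"mean_viability_fc"`).
#' @export
phenotype_response <- function(fit_mut = NULL, fit_wt = NULL,
                               viability_ratio = NULL) {
  both <- !is.null(fit_mut) && !is.null(fit_wt) &&
    isTRUE(fit_mut$converged) && isTRUE(fit_wt$converged)
  if (both) {
    return(list(response_fc = fit_mut$ic50 / fit_wt$ic50,
                basis = "ic50_ratio"))
  }
  if (is.null(viability_ratio) || length(viability_ratio) == 0L) {
    abort_data("no converged fits and no screen viability ratios supplied")
  }
  list(response_fc = mean(viability_ratio), basis = "mean_viability_fc")
}

#' Phenotypic responses for all drugs of a normalized screen
#'
#' For each drug, fits 4PL curves per genotype from the treated-well
#' viabilities and applies the two-tier rule of [phenotype_response()].
#'
#' @param viability Normalized plate table (from [normalize_plates()]) with
#'   `role == "treated"` rows carrying `drug`, `dose_uM`, `genotype`,
#'   `viability`.
#' @param genotypes Length-2 character vector `c(mutant, wild_type)` naming
#'   the genotype levels. Default `c("mutant", "wild_type")`.
#' @return A tibble (`drug`, `response_fc`, `basis`, `ic50_mut`, `ic50_wt`).
#'   Drugs missing a genotype are skipped with a warning.
#' @export
screen_phenotypes <- function(viability,
                              genotypes = c("mutant", "wild_type")) {
  need_cols(viability, c("role", "drug", "dose_uM", "genotype", "viability"),
            "viability table")
  tr <- viability[viability$role == "treated" & !is.na(viability$drug), ,
                  drop = FALSE]
  if (nrow(tr) == 0L) abort_data("no treated wells in the viability table")
  drugs <- sort(unique(tr$drug))
  skipped <- character(0)
  rows <- lapply(drugs, function(d) {
    w <- tr[tr$drug == d, , drop = FALSE]
    wm <- w[w$genotype == genotypes[1L], ]
    ww <- w[w$genotype == genotypes[2L], ]
    if (nrow(wm) == 0L || nrow(ww) == 0L) {
      skipped <<- c(skipped, d)
      return(NULL)
    }
    fm <- tryCatch(fit_dose_response(wm$dose_uM, wm$viability),
                   revsig_data_error = function(e) NULL)
    fw <- tryCatch(fit_dose_response(ww$dose_uM, ww$viability),
                   revsig_data_error = function(e) NULL)
    mm <- tapply(wm$viability, wm$dose_uM, mean)
    mw <- tapply(ww$viability, ww$dose_uM, mean)
    common <- intersect(names(mm), names(mw))
    resp <- phenotype_response(fm, fw, viability_ratio = mm[common] / mw[common])
    tibble::tibble(drug = d, response_fc = resp$response_fc,
                   basis = resp$basis,
                   ic50_mut = if (!is.null(fm) && fm$converged) fm$ic50 else NA_real_,
                   ic50_wt = if (!is.null(fw) && fw$converged) fw$ic50 else NA_real_)
  })
  if (length(skipped) > 0L) {
    warning(sprintf("skipped %d drug(s) missing a genotype: %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Correlate phenotypic response with predicted reversal
#'
#' Joins per-drug phenotypic response fold-changes with per-drug sRGES and
#' assigns each drug to a concordance class:
#'
#' * **I** — responsive by both measures: `response_fc <= sens_fc_max` and
#'   `srges < srges_neg_max`;
#' * **II** — responsive by sensitivity but not by predicted reversal:
#'   `response_fc <= sens_fc_max`, `srges >= srges_neg_max`;
#' * **III** — non-responsive by both: `response_fc >= 1 / sens_fc_max` and
#'   `srges >= srges_neg_max`;
#' * **neutral** — everything else.
#'
#' Also reports the Spearman rank correlation between `log(response_fc)`
#' and sRGES.
#'
#' @param phenotypes Tibble (`drug`, `response_fc`, ...), e.g. from
#'   [screen_phenotypes()].
#' @param srges Tibble (`drug`, `srges`).
#' @param sens_fc_max Sensitivity cutoff on the response fold-change
#'   (default 0.67, i.e. ~1.5-fold sensitization).
#' @param srges_neg_max sRGES cutoff for "predicted reverser" (default 0).
#' @return A list of class `"prediction_correlation"`: `records` (joined
#'   tibble with `cls`), `spearman_rho`, `spearman_p`, and the thresholds.
#' @export
correlate_prediction <- function(phenotypes, srges, sens_fc_max = 0.67,
                                 srges_neg_max = 0) {
  need_cols(phenotypes, c("drug", "response_fc"), "phenotype table")
  need_cols(srges, c("drug", "srges"), "sRGES table")
  rec <- dplyr::inner_join(phenotypes,
                           dplyr::select(srges, "drug", "srges"),
                           by = "drug")
  if (nrow(rec) == 0L) abort_data("no drug shared between phenotype and sRGES tables")
  sensitive <- rec$response_fc <= sens_fc_max
  resistant <- rec$response_fc >= 1 / sens_fc_max
  reverser <- rec$srges < srges_neg_max
  rec$cls <- dplyr::case_when(
    sensitive & reverser ~ "I",
    sensitive & !reverser ~ "II",
    resistant & !reverser ~ "III",
    .default = "neutral")
  ct <- suppressWarnings(
    cor.test(log(rec$response_fc), rec$srges, method = "spearman"))
  structure(list(records = dplyr::arrange(rec, .data$cls, .data$drug),
                 spearman_rho = unname(ct$estimate),
                 spearman_p = ct$p.value,
                 sens_fc_max = sens_fc_max, srges_neg_max = srges_neg_max),
            class = "prediction_correlation")
}

#' @export
print.prediction_correlation <- function(x, ...) {
  cat(sprintf("<prediction_correlation> %d drugs; Spearman rho = %.3f (p = %.3g)\n",
              nrow(x$records), x$spearman_rho, x$spearman_p))
  print(table(x$records$cls))
  invisible(x)
}

#' Cluster screen response patterns
#'
#' Agglomerative hierarchical clustering of the drugs-by-conditions
#' viability matrix with correlation distance (1 - Pearson) and average
#' linkage, cut at `k` clusters — the standard view for grouping screen
#' response archetypes. Missing values are imputed by row median;
#' zero-variance rows get distance 1 to everything.
#'
#' @param mat Numeric matrix, drugs x (genotype, dose) conditions.
#' @param k Number of clusters (1 <= k <= nrow(mat)).
#' @return Named integer vector of cluster labels (one per row of `mat`).
#' @export
cluster_screen <- function(mat, k = 3) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort_config("`mat` must be a numeric matrix")
  if (!is_count(k) || k < 1 || k > nrow(mat)) {
    abort_config("`k` must be an integer within 1..nrow(mat)")
  }
  for (i in seq_len(nrow(mat))) {
    na <- is.na(mat[i, ])
    if (any(na)) mat[i, na] <- median(mat[i, ], na.rm = TRUE)
  }
  if (k == 1L) {
    return(setNames(rep(1L, nrow(mat)), rownames(mat)))
  }
  cc <- suppressWarnings(cor(t(mat)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  cutree(hc, k = k)
}

#' Read a plate table from TSV
#'
#' @param path TSV with columns `plate`, `well`, `role`, `drug`, `dose_uM`,
#'   `genotype`, `signal`.
#' @return A tibble.
#' @export
read_plates <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(tab, c("plate", "well", "role", "drug", "dose_uM", "genotype",
                   "signal"), sprintf("plate table '%s'", path))
  tab
}
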