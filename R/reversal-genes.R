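# Reversal genes: signature genes whose drug-induced fold-change opposes
# their disease direction. Two analyses are provided: class-level reversal
# fractions (which signature genes does a drug class reverse consistently),
# and a rank-based comparison of phenotype-sensitive versus insensitive drug
# classes that pinpoints the genes whose reversal tracks drug efficacy.

#' Flag per-profile reversal of signature genes
#'
#' A disease-up gene is reversed by a profile when its drug fold-change is
#' strictly negative; a disease-down gene when strictly positive. A
#' fold-change of exactly zero is not a reversal.
#'
#' @param fc Named numeric vector of per-gene fold-changes for one profile.
#' @param sig A [disease_signature()].
#' @return A tibble (`gene`, `direction`, `fc`, `reversed`) covering the
#'   signature genes present in the profile.
#' @export
flag_reversals <- function(fc, sig) {
  if (!inherits(sig, "disease_signature")) {
    abort_config("`sig` must be a disease_signature")
  }
  genes <- c(sig$up, sig$down)
  direction <- rep(c("up", "down"), c(length(sig$up), length(sig$down)))
  present <- genes %in% names(fc)
  genes <- genes[present]; direction <- direction[present]
  val <- unname(fc[genes])
  tibble::tibble(
    gene = genes, direction = direction, fc = val,
    reversed = ifelse(direction == "up", val < 0, val > 0))
}

#' Genes consistently reversed by a drug class
#'
#' Computes, for every signature gene, the fraction of the class's profiles
#' that reverse it (over the profiles containing the gene) and selects genes
#' reversed in *more than* `min_fraction` of them (strict inequality).
#'
#' @param profiles Long-form profile tibble for the class's drugs.
#' @param sig A [disease_signature()].
#' @param min_fraction Strict lower bound on the reversal fraction.
#'   Default 0.6.
#' @return A tibble (`gene`, `direction`, `n_profiles`, `reversal_fraction`,
#'   `selected`). Signature genes absent from every profile are excluded.
#' @export
class_reversal_genes <- function(profiles, sig, min_fraction = 0.6) {
  need_cols(profiles, c("drug", "cell_line", "dose_uM", "time_h", "gene", "fc"),
            "profile table")
  if (nrow(profiles) == 0L) abort_data("profile table is empty")
  idx <- split(seq_len(nrow(profiles)), profile_id(profiles))
  flags <- lapply(idx, function(i) {
    flag_reversals(setNames(profiles$fc[i], profiles$gene[i]), sig)
  })
  all_flags <- dplyr::bind_rows(flags)
  if (nrow(all_flags) == 0L) {
    abort_data("no signature gene is present in any profile")
  }
  all_flags |>
    dplyr::group_by(.data$gene, .data$direction) |>
    dplyr::summarise(n_profiles = dplyr::n(),
                     reversal_fraction = mean(.data$reversed),
                     .groups = "drop") |>
    dplyr::mutate(selected = .data$reversal_fraction > min_fraction) |>
    dplyr::arrange(dplyr::desc(.data$reversal_fraction), .data$gene)
}

#' One-sided Mann-Whitney-Wilcoxon test
#'
#' Thin wrapper over [stats::wilcox.test()] exposing the exact and
#' normal-approximation routes separately. `"auto"` uses the exact
#' distribution for tie-free samples with both group sizes at most 8 and
#' the normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"` (x tends larger) or `"less"`.
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @return A list with `u` (the U statistic of `x` versus `y`) and `p`.
#' @export
mww_test <- function(x, y, alternative = c("greater", "less"),
                     method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) < 1L || length(y) < 1L) abort_data("both samples must be non-empty")
  exact_ok <- length(x) <= 8L && length(y) <= 8L &&
    anyDuplicated(c(x, y)) == 0L
  exact <- switch(method, auto = exact_ok, exact = TRUE, normal = FALSE)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact))
  list(u = unname(wt$statistic), p = wt$p.value)
}

# Normalized within-profile expression ranks for a set of genes.
# Returns a genes x profiles matrix of (rank - 1) / (n - 1), rank 1 = most
# up-regulated by the drug; NA where a gene is absent from a profile.
profile_rank_matrix <- function(profiles, genes) {
  idx <- split(seq_len(nrow(profiles)), profile_id(profiles))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(idx),
                dimnames = list(genes, names(idx)))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    g <- profiles$gene[i]
    n <- length(g)
    if (n < 2L) next
    r <- integer(n)
    r[order_radix(-profiles$fc[i], g)] <- seq_len(n)
    hit <- match(genes, g)
    mat[!is.na(hit), k] <- (r[hit[!is.na(hit)]] - 1) / (n - 1)
  }
  mat
}

# Per-profile reversal indicator matrix (genes x profiles), NA when absent.
profile_reversal_matrix <- function(profiles, sig) {
  genes <- c(sig$up, sig$down)
  dir_up <- c(rep(TRUE, length(sig$up)), rep(FALSE, length(sig$down)))
  idx <- split(seq_len(nrow(profiles)), profile_id(profiles))
  mat <- matrix(NA, nrow = length(genes), ncol = length(idx),
                dimnames = list(genes, names(idx)))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    hit <- match(genes, profiles$gene[i])
    val <- profiles$fc[i][hit]
    mat[, k] <- ifelse(dir_up, val < 0, val > 0)
  }
  mat
}

#' Reversal genes discriminating sensitive from insensitive drug classes
#'
#' Compares, gene by gene, the within-profile expression ranks of signature
#' genes between profiles of phenotype-sensitive drug classes and profiles
#' of insensitive classes. For a disease-up gene the one-sided alternative
#' is that the sensitive group pushes the gene toward the down-regulated end
#' of the drug ranking (larger normalized rank); for a disease-down gene,
#' toward the up-regulated end (smaller normalized rank). P-values come from
#' the one-sided Mann-Whitney-Wilcoxon test ([mww_test()]) and are adjusted
#' across all tested signature genes with the Benjamini-Hochberg step-up
#' procedure. A gene is selected when `fdr <= fdr_max` *and* it is reversed
#' in at least `min_fraction` (inclusive) of the pooled sensitive-class
#' profiles containing it.
#'
#' @param profiles_sensitive,profiles_insensitive Long-form profile tibbles
#'   for the two drug groups (both non-empty).
#' @param sig A [disease_signature()].
#' @param fdr_max FDR cutoff for selection. Default 0.25.
#' @param min_fraction Inclusive reversal-fraction cutoff within the
#'   sensitive profiles. Default 0.6.
#' @param statistic Per-profile gene statistic: `"rank"` (normalized
#'   within-profile expression rank, default; robust across universes of
#'   different size) or `"fc"` (raw fold-change).
#' @param method Test method passed to [mww_test()].
#' @return A tibble with one row per signature gene present in the data:
#'   `gene`, `direction`, `n_sensitive`, `n_insensitive`, `u_stat`, `p`,
#'   `fdr`, `reversal_fraction`, `selected`, `tested` (genes seen in fewer
#'   than 2 profiles per group are reported untested).
#' @export
sensitive_vs_insensitive <- function(profiles_sensitive, profiles_insensitive,
                                     sig, fdr_max = 0.25, min_fraction = 0.6,
                                     statistic = c("rank", "fc"),
                                     method = c("auto", "exact", "normal")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (nrow(profiles_sensitive) == 0L || nrow(profiles_insensitive) == 0L) {
    abort_data("both profile groups must be non-empty")
  }
  genes <- c(sig$up, sig$down)
  if (length(genes) == 0L) abort_data("signature is empty")
  direction <- rep(c("up", "down"), c(length(sig$up), length(sig$down)))
  if (statistic == "rank") {
    xs <- profile_rank_matrix(profiles_sensitive, genes)
    xi <- profile_rank_matrix(profiles_insensitive, genes)
    # larger normalized rank = closer to the down-regulated end
    alt_up <- "greater"; alt_down <- "less"
  } else {
    xs <- fc_matrix(profiles_sensitive, genes)
    xi <- fc_matrix(profiles_insensitive, genes)
    # smaller fc = pushed down
    alt_up <- "less"; alt_down <- "greater"
  }
  rev_sens <- profile_reversal_matrix(profiles_sensitive, sig)
  res <- lapply(seq_along(genes), function(g) {
    x <- xs[g, ]; x <- x[!is.na(x)]
    y <- xi[g, ]; y <- y[!is.na(y)]
    rv <- rev_sens[g, ]; rv <- rv[!is.na(rv)]
    frac <- if (length(rv) > 0L) mean(rv) else NA_real_
    base <- tibble::tibble(gene = genes[g], direction = direction[g],
                           n_sensitive = length(x), n_insensitive = length(y),
                           reversal_fraction = frac)
    if (length(x) < 2L || length(y) < 2L) {
      return(dplyr::mutate(base, u_stat = NA_real_, p = NA_real_,
                           tested = FALSE))
    }
    alt <- if (direction[g] == "up") alt_up else alt_down
    tst <- mww_test(x, y, alternative = alt, method = method)
    dplyr::mutate(base, u_stat = tst$u, p = tst$p, tested = TRUE)
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out$selected <- out$tested & !is.na(out$fdr) & out$fdr <= fdr_max &
    !is.na(out$reversal_fraction) & out$reversal_fraction >= min_fraction
  dplyr::select(out, "gene", "direction", "n_sensitive", "n_insensitive",
                "u_stat", "p", "fdr", "reversal_fraction", "selected",
                "tested") |>
    dplyr::arrange(.data$p, .data$gene)
}

# Per-profile fold-change matrix (genes x profiles), NA when absent.
fc_matrix <- function(profiles, genes) {
  idx <- split(seq_len(nrow(profiles)), profile_id(profiles))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(idx),
                dimnames = list(genes, names(idx)))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    hit <- match(genes, profiles$gene[i])
    mat[, k] <- profiles$fc[i][hit]
  }
  mat
}

#' Mean fold-change matrix of genes by drug class
#'
#' Builds the genes-by-classes matrix of mean fold-changes used to display
#' which signature genes each candidate class reverses (each drug
#' contributes its across-condition mean fold-change, averaged within the
#' class).
#'
#' @param profiles Long-form profile tibble.
#' @param moa Tibble (`drug`, `moa_class`).
#' @param genes Character vector of genes (rows of the result).
#' @return A numeric matrix, genes x classes.
#' @export
class_mean_fc_matrix <- function(profiles, moa, genes) {
  need_cols(moa, c("drug", "moa_class"), "MOA table")
  per_drug <- mean_gene_fc(profiles[profiles$gene %in% genes, , drop = FALSE])
  per_drug$moa_class <- moa$moa_class[match(per_drug$drug, moa$drug)]
  per_drug <- per_drug[!is.na(per_drug$moa_class), , drop = FALSE]
  agg <- per_drug |>
    dplyr::group_by(.data$moa_class, .data$gene) |>
    dplyr::summarise(mean_fc = mean(.data$mean_fc), .groups = "drop")
  classes <- sort(unique(agg$moa_class))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(classes),
                dimnames = list(genes, classes))
  mat[cbind(match(agg$gene, genes), match(agg$moa_class, classes))] <- agg$mean_fc
  mat
}
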