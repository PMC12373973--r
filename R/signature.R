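#' Differential-expression filtering thresholds
#'
#' Bundle of thresholds used by [build_signature()] to call up- and
#' down-regulated genes from a differential-expression table. Two modes are
#' supported: `"log2fc"` selects genes with `fdr <= fdr_max` and
#' `|log2fc| >= abs_log2fc_min`; `"fc"` selects genes with `fdr <= fdr_max`
#' and linear fold-change `fc >= fc_up_min` (up) or `fc <= fc_down_max`
#' (down).
#'
#' @param fdr_max Maximum false-discovery rate, in (0, 1]. Default 0.05.
#' @param abs_log2fc_min Minimum absolute log2 fold-change (log2fc mode).
#'   Default 0.5.
#' @param fc_up_min Minimum linear fold-change for up-regulation (fc mode).
#'   Must exceed 1. Default 1.2.
#' @param fc_down_max Maximum linear fold-change for down-regulation (fc
#'   mode). Must lie in (0, 1). Default 0.8.
#' @param mode `"log2fc"` or `"fc"`.
#' @return A list of class `"signature_thresholds"`.
#' @export
signature_thresholds <- function(fdr_max = 0.05, abs_log2fc_min = 0.5,
                                 fc_up_min = 1.2, fc_down_max = 0.8,
                                 mode = c("log2fc", "fc")) {
  mode <- match.arg(mode)
  if (!is_scalar_number(fdr_max) || fdr_max <= 0 || fdr_max > 1) {
    abort_config("`fdr_max` must be in (0, 1]")
  }
  if (!is_scalar_number(abs_log2fc_min) || abs_log2fc_min < 0) {
    abort_config("`abs_log2fc_min` must be >= 0")
  }
  if (!is_scalar_number(fc_up_min) || !is_scalar_number(fc_down_max) ||
      !(fc_up_min > 1 && 1 > fc_down_max && fc_down_max > 0)) {
    abort_config("need fc_up_min > 1 > fc_down_max > 0")
  }
  structure(list(fdr_max = fdr_max, abs_log2fc_min = abs_log2fc_min,
                 fc_up_min = fc_up_min, fc_down_max = fc_down_max,
                 mode = mode),
            class = "signature_thresholds")
}

#' Build a disease signature from a differential-expression table
#'
#' Applies FDR and effect-size thresholds to a differential-expression table
#' and returns the paired up- and down-regulated gene sets that define the
#' disease state. Genes inside each set are ordered by descending effect
#' magnitude; the downstream reversal score is insensitive to that order, it
#' only fixes a deterministic output.
#'
#' @param table Data frame with columns `gene`, `fdr`, and `log2fc`
#'   (log2fc mode) or `fc` (fc mode; linear fold-change > 0). One row per
#'   gene.
#' @param thresholds A [signature_thresholds()] object.
#' @param name Label for the signature.
#' @return An object of class `"disease_signature"`: a list with `name`,
#'   `up`, and `down` (character vectors of gene symbols, disjoint). If
#'   either side is empty a warning is emitted and the signature is flagged
#'   via the attribute `"empty_side"`.
#' @examples
#' tab <- data.frame(gene = c("A", "B"), log2fc = c(0.9, -0.8),
#'                   fdr = c(0.01, 0.02))
#' build_signature(tab, signature_thresholds())
#' @export
build_signature <- function(table, thresholds = signature_thresholds(),
                            name = "signature") {
  if (!inherits(thresholds, "signature_thresholds")) {
    abort_config("`thresholds` must come from signature_thresholds()")
  }
  if (nrow(table) == 0L) abort_data("differential-expression table is empty")
  need_cols(table, c("gene", "fdr"), "DE table")
  if (anyDuplicated(table$gene) > 0L) {
    abort_data("DE table must have one row per gene")
  }
  if (any(is.na(table$fdr)) || any(table$fdr < 0 | table$fdr > 1)) {
    abort_data("`fdr` must be within [0, 1] and non-missing")
  }
  if (thresholds$mode == "log2fc") {
    need_cols(table, "log2fc", "DE table (log2fc mode)")
    effect <- table$log2fc
    up <- table$fdr <= thresholds$fdr_max & effect >= thresholds$abs_log2fc_min
    down <- table$fdr <= thresholds$fdr_max & effect <= -thresholds$abs_log2fc_min
    magnitude <- abs(effect)
  } else {
    need_cols(table, "fc", "DE table (fc mode)")
    if (any(table$fc <= 0)) abort_data("`fc` must be positive (linear fold-change)")
    effect <- table$fc
    up <- table$fdr <= thresholds$fdr_max & effect >= thresholds$fc_up_min
    down <- table$fdr <= thresholds$fdr_max & effect <= thresholds$fc_down_max
    magnitude <- abs(log2(effect))
  }
  up_genes <- table$gene[up][order_radix(-magnitude[up], table$gene[up])]
  down_genes <- table$gene[down][order_radix(-magnitude[down], table$gene[down])]
  empty_side <- c("up", "down")[c(length(up_genes) == 0L, length(down_genes) == 0L)]
  if (length(empty_side) > 0L) {
    warning(sprintf("signature '%s' has no genes on side(s): %s",
                    name, paste(empty_side, collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, up = up_genes, down = down_genes),
            class = "disease_signature",
            thresholds = thresholds,
            empty_side = empty_side)
}

#' Construct a disease signature directly from gene sets
#'
#' @param up,down Character vectors of up- and down-regulated gene symbols
#'   (disjoint).
#' @param name Label for the signature.
#' @return A `"disease_signature"` object.
#' @export
disease_signature <- function(up, down, name = "signature") {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)) > 0L) {
    abort_data("`up` and `down` gene sets must be disjoint")
  }
  if (anyDuplicated(up) > 0L || anyDuplicated(down) > 0L) {
    abort_data("gene sets must not contain duplicates")
  }
  structure(list(name = name, up = up, down = down),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature> '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Map signature gene symbols to homologs
#'
#' Replaces each signature gene by its homolog from a user-supplied mapping
#' table (e.g., mouse-to-human symbol conversion so a rodent-derived disease
#' signature can be scored against a human drug-profile gene universe).
#' Unmapped genes are dropped, or upper-cased when `fallback_uppercase` is
#' set (the common rodent-to-human symbol heuristic). Duplicate targets are
#' collapsed keeping the first occurrence; a target mapped from both the up
#' and the down side is removed from both sides with a warning, preserving
#' disjointness.
#'
#' @param sig A `"disease_signature"`.
#' @param map Data frame with columns `source` and `target` (many-to-one
#'   allowed; one source must not map to two targets), or a named character
#'   vector `c(source = target)`.
#' @param fallback_uppercase If `TRUE`, genes absent from `map` are
#'   upper-cased instead of dropped.
#' @return The mapped `"disease_signature"`, with attribute `"n_dropped"`
#'   recording how many input genes were lost (unmapped or conflicting).
#' @export
map_homologs <- function(sig, map, fallback_uppercase = FALSE) {
  if (!inherits(sig, "disease_signature")) {
    abort_config("`sig` must be a disease_signature")
  }
  if (is.character(map) && !is.null(names(map))) {
    map <- data.frame(source = names(map), target = unname(map))
  }
  need_cols(map, c("source", "target"), "homolog map")
  by_source <- split(map$target, map$source)
  if (any(vapply(by_source, function(t) length(unique(t)), 1L) > 1L)) {
    abort_data("homolog map sends one source symbol to multiple targets")
  }
  translate <- function(genes) {
    idx <- match(genes, map$source)
    out <- map$target[idx]
    if (fallback_uppercase) out[is.na(idx)] <- toupper(genes[is.na(idx)])
    out <- out[!is.na(out)]
    out[!duplicated(out)]
  }
  up <- translate(sig$up)
  down <- translate(sig$down)
  clash <- intersect(up, down)
  if (length(clash) > 0L) {
    warning(sprintf("homolog mapping sent %d target(s) to both sides; dropped: %s",
                    length(clash), paste(clash, collapse = ", ")), call. = FALSE)
    up <- setdiff(up, clash)
    down <- setdiff(down, clash)
  }
  n_dropped <- (length(sig$up) + length(sig$down)) - (length(up) + length(down))
  structure(list(name = sig$name, up = up, down = down),
            class = "disease_signature", n_dropped = n_dropped)
}

#' Read a differential-expression table from TSV
#'
#' Expects at least columns `gene`, `fdr`, and `log2fc` and/or `fc`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(tab, c("gene", "fdr"), sprintf("DE table '%s'", path))
  tab
}

#' Write a disease signature to disk
#'
#' Writes a two-column TSV (`gene`, `direction`) and, when `json` is `TRUE`,
#' a JSON file with the same content next to it.
#'
#' @param sig A `"disease_signature"`.
#' @param path Output TSV path.
#' @param json Also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, json = FALSE) {
  tab <- tibble::tibble(
    gene = c(sig$up, sig$down),
    direction = rep(c("up", "down"), c(length(sig$up), length(sig$down)))
  )
  readr::write_tsv(tab, path, progress = FALSE)
  if (json) {
    jsonlite::write_json(list(name = sig$name, up = sig$up, down = sig$down),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
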