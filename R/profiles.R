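# Drug-response expression profiles are handled as a long table with one row
# per (profile, gene): columns drug, cell_line, dose_uM, time_h, gene, fc.
# A profile is one treatment condition of one drug; its ranking (rank 1 =
# gene most up-regulated by the drug) is derived from fc, ties broken by
# gene symbol in C-locale order so rank lists are total orders.

profile_id <- function(profiles) {
  paste(profiles$drug, profiles$cell_line, profiles$dose_uM, profiles$time_h,
        sep = "\r")
}

#' Read drug-response profiles from a long TSV
#'
#' @param path TSV with columns `drug`, `cell_line`, `dose_uM`, `time_h`,
#'   `gene`, `fc`.
#' @return A tibble of profiles in long form.
#' @export
read_profiles <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(tab, c("drug", "cell_line", "dose_uM", "time_h", "gene", "fc"),
            sprintf("profile table '%s'", path))
  tab
}

#' Read a wide profile matrix TSV
#'
#' First column `gene`, remaining columns one per profile named
#' `drug|cell_line|dose_uM|time_h`. Returns the long form used by the rest
#' of the package.
#'
#' @param path TSV path.
#' @param sep Separator inside the profile column names. Default `"|"`.
#' @return A long-form tibble of profiles.
#' @export
read_profiles_wide <- function(path, sep = "|") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(tab, "gene", sprintf("wide profile table '%s'", path))
  long <- tidyr::pivot_longer(tab, -"gene", names_to = "profile",
                              values_to = "fc")
  parts <- strsplit(long$profile, sep, fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    abort_data("wide profile column names must be drug|cell_line|dose_uM|time_h")
  }
  m <- do.call(rbind, parts)
  tibble::tibble(drug = m[, 1L], cell_line = m[, 2L],
                 dose_uM = as.numeric(m[, 3L]), time_h = as.numeric(m[, 4L]),
                 gene = long$gene, fc = long$fc)
}

#' Parse a GCT-dialect expression matrix (parse only)
#'
#' Minimal reader for the versioned GCT text format: a `#1.x` version line, a
#' dimensions line, then a header row and one row per gene. Row/column
#' metadata columns (GCT 1.3) are returned separately; no writing support.
#'
#' @param path Path to a `.gct` file.
#' @return A list with `matrix` (numeric, genes x samples), `row_meta`
#'   (tibble) and `version`.
#' @export
read_gct <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.")) {
    abort_data(sprintf("'%s' is not a GCT file (missing #1.x version line)", path))
  }
  version <- sub("^#", "", lines[1L])
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]])
  if (length(dims) < 2L || any(is.na(dims[1:2]))) {
    abort_data("malformed GCT dimensions line")
  }
  nr <- dims[1L]; nc <- dims[2L]
  # 1.2 always has id + description columns; 1.3 has id + declared row-meta
  n_ann <- if (startsWith(version, "1.3") && length(dims) >= 3L) {
    1L + dims[3L]
  } else {
    2L
  }
  body <- readr::read_tsv(I(lines[-(1:2)]), show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(body) < nr) abort_data("GCT body has fewer rows than declared")
  id_cols <- seq_len(n_ann)
  data_cols <- seq(length(id_cols) + 1L, length.out = nc)
  mat <- as.matrix(body[seq_len(nr), data_cols])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(body[[1L]][seq_len(nr)])
  list(matrix = mat, row_meta = body[seq_len(nr), id_cols], version = version)
}

#' Restrict profiles to a cell-line whitelist
#'
#' The reversal-score screen can be limited to profiles from lineages that
#' resemble the disease model (e.g., hematopoietic lines for a leukemia
#' signature).
#'
#' @param profiles Long-form profile tibble.
#' @param cell_lines Non-empty character vector of cell lines to keep.
#' @return The filtered tibble; warns if nothing is left.
#' @export
filter_profiles <- function(profiles, cell_lines) {
  if (length(cell_lines) == 0L) {
    abort_config("`cell_lines` whitelist must be non-empty")
  }
  need_cols(profiles, "cell_line", "profile table")
  out <- profiles[profiles$cell_line %in% cell_lines, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no profiles left after cell-line filtering", call. = FALSE)
  }
  out
}
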