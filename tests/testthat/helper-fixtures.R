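# Small in-code fixture builders shared across test files.

# One profile as a long tibble from a named fc vector.
profile_tbl <- function(fc, drug = "d1", cell_line = "HL60",
                        dose_uM = 10, time_h = 24) {
  tibble::tibble(drug = drug, cell_line = cell_line, dose_uM = dose_uM,
                 time_h = time_h, gene = names(fc), fc = unname(fc))
}

# Several profiles: `fcs` is a named list of named fc vectors; names become
# profile indices mapped onto distinct doses of one drug unless `meta` rows
# are supplied.
profiles_tbl <- function(fcs, drug = "d1", meta = NULL) {
  if (is.null(meta)) {
    meta <- tibble::tibble(drug = drug, cell_line = "HL60",
                           dose_uM = seq_along(fcs), time_h = 24)
  }
  dplyr::bind_rows(lapply(seq_along(fcs), function(i) {
    profile_tbl(fcs[[i]], drug = meta$drug[i], cell_line = meta$cell_line[i],
                dose_uM = meta$dose_uM[i], time_h = meta$time_h[i])
  }))
}

# Profile with the signature sets placed at exact rank positions within a
# universe of size n (positions 1 = most up-regulated).
profile_at_positions <- function(n, up_pos = integer(0), down_pos = integer(0),
                                 up_genes = sprintf("U%02d", seq_along(up_pos)),
                                 down_genes = sprintf("D%02d", seq_along(down_pos))) {
  genes <- sprintf("N%03d", seq_len(n))
  genes[up_pos] <- up_genes
  genes[down_pos] <- down_genes
  setNames(seq(n, 1), genes)  # fc decreasing => gene at index i has rank i
}

# A 6-row DE table with hand-enumerated pass/fail pattern:
#   log2fc mode (FDR<=0.05, |log2FC|>=0.5): up = {A, B}, down = {C}
#   fc mode (FDR<=0.05, FC>=1.2 or <=0.8):  up = {A, B, E}, down = {C}
toy_de_table <- function() {
  tab <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E", "F"),
    log2fc = c(0.9, 0.6, -0.7, 0.6, 0.3, -0.4),
    fdr = c(0.01, 0.04, 0.02, 0.06, 0.01, 0.20))
  tab$fc <- 2^tab$log2fc
  tab
}
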