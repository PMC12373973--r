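make_plate <- function(signals_treated, dmso = 1, empty = 0.05,
                       plate = "p1", drug = "dr1",
                       doses = seq_along(signals_treated)) {
  tibble::tibble(
    plate = plate,
    well = sprintf("W%02d", seq_len(length(signals_treated) + 4)),
    role = c(rep("treated", length(signals_treated)),
             "dmso", "dmso", "empty", "empty"),
    drug = c(rep(drug, length(signals_treated)), rep(NA, 4)),
    dose_uM = c(doses, rep(NA, 4)),
    genotype = "wild_type",
    signal = c(signals_treated, dmso, dmso, empty, empty))
}

test_that("plate normalization maps DMSO to 1, empty to 0, midpoint to 0.5", {
  pl <- make_plate(c(1, 0.05, 0.525))
  v <- normalize_plates(pl)
  tr <- v$viability[v$role == "treated"]
  expect_equal(tr, c(1, 0, 0.5))
  expect_equal(unique(v$viability[v$role == "dmso"]), 1)
  expect_equal(unique(v$viability[v$role == "empty"]), 0)
})

test_that("normalization is invariant to per-plate affine rescaling", {
  withr::with_seed(61, {
    pl <- make_plate(runif(6, 0.1, 0.9))
    v1 <- normalize_plates(pl)$viability
    pl2 <- pl
    pl2$signal <- 3.7 * pl$signal + 11
    v2 <- normalize_plates(pl2)$viability
    expect_equal(v1, v2, tolerance = 1e-12)
  })
})

test_that("broken plates abort with a data error", {
  bad <- make_plate(c(0.5, 0.6), dmso = 0.04, empty = 0.05)
  expect_error(normalize_plates(bad), class = "revsig_data_error")
  no_ctrl <- make_plate(c(0.5, 0.6))
  no_ctrl <- no_ctrl[no_ctrl$role != "empty", ]
  expect_error(normalize_plates(no_ctrl), class = "revsig_data_error")
})

test_that("noiseless 4PL data is recovered within 1% relative error", {
  doses <- 10^seq(-2, 1, length.out = 8)
  v <- fourpl_oracle(doses, top = 1, bottom = 0, ic50 = 1, hill = 1)
  fit <- fit_dose_response(doses, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 1) / 1, 0.01)
  expect_equal(fit$hill, 1, tolerance = 0.05)
})

test_that("rescaling doses rescales the fitted IC50 and nothing else", {
  doses <- 10^seq(-2, 1, length.out = 8)
  v <- fourpl_oracle(doses, top = 1, bottom = 0.1, ic50 = 0.5, hill = 1.5)
  f1 <- fit_dose_response(doses, v)
  f2 <- fit_dose_response(doses * 20, v)
  expect_equal(f2$ic50 / f1$ic50, 20, tolerance = 1e-3)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-3)
  expect_equal(f2$top, f1$top, tolerance = 1e-3)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-3)
})

test_that("flat or invalid dose-response input is handled honestly", {
  fit <- fit_dose_response(c(0.1, 1, 10, 100), rep(1, 4))
  expect_false(fit$converged)
  expect_identical(fit$reason, "flat_response")
  expect_error(fit_dose_response(c(1, 2, 3), c(1, 0.5, 0)),
               class = "revsig_data_error")
  expect_error(fit_dose_response(c(-1, 1, 2, 3), c(1, 0.8, 0.5, 0)),
               class = "revsig_data_error")
})

test_that("two-tier phenotype response rule", {
  fit_m <- structure(list(ic50 = 1, converged = TRUE), class = "dose_response_fit")
  fit_w <- structure(list(ic50 = 4, converged = TRUE), class = "dose_response_fit")
  r <- phenotype_response(fit_m, fit_w)
  expect_equal(r$response_fc, 0.25)
  expect_identical(r$basis, "ic50_ratio")

  r2 <- phenotype_response(NULL, fit_w,
                           viability_ratio = c(0.8, 0.9, 1.0, 1.1, 1.2))
  expect_equal(r2$response_fc, 1.0)
  expect_identical(r2$basis, "mean_viability_fc")

  r3 <- phenotype_response(fit_w, fit_w)
  expect_equal(r3$response_fc, 1.0)
  expect_error(phenotype_response(NULL, NULL), class = "revsig_data_error")
})

test_that("concordance classes follow the decision rule", {
  phen <- tibble::tibble(drug = c("a", "b", "c", "d"),
                         response_fc = c(0.4, 0.4, 2.0, 1.0))
  srg <- tibble::tibble(drug = c("a", "b", "c", "d"),
                        srges = c(-0.3, 0.2, 0.2, -0.1))
  corr <- correlate_prediction(phen, srg, sens_fc_max = 0.67)
  cls <- setNames(corr$records$cls, corr$records$drug)
  expect_identical(cls[["a"]], "I")
  expect_identical(cls[["b"]], "II")
  expect_identical(cls[["c"]], "III")
  expect_identical(cls[["d"]], "neutral")
  expect_error(correlate_prediction(phen, tibble::tibble(drug = "zz", srges = 0)),
               class = "revsig_data_error")
})

test_that("screen clustering recovers planted response archetypes", {
  withr::with_seed(62, {
    arch <- rbind(seq(1, 0, length.out = 10),             # decline
                  seq(0, 1, length.out = 10),             # stimulation
                  c(seq(1, 0, length.out = 5),
                    seq(0.2, 1, length.out = 5)))         # rebound
    mat <- arch[rep(1:3, each = 6), ] + rnorm(180, 0, 0.015)
    rownames(mat) <- sprintf("drug%02d", 1:18)
    labels <- cluster_screen(mat, k = 3)
    expect_true(same_partition(labels, rep(1:3, each = 6)))

    expect_identical(unique(cluster_screen(mat, k = 1)), 1L)
    dup <- mat[c(1, 1, 7, 13), ]
    lab_dup <- cluster_screen(dup, k = 3)
    expect_identical(lab_dup[[1]], lab_dup[[2]])
    expect_error(cluster_screen(mat, k = 99), class = "revsig_config_error")
  })
})

test_that("missing values are imputed by row median before clustering", {
  mat <- rbind(c(1, NA, 0.8, 0.2, 0), c(1, 0.9, NA, 0.2, 0),
               c(0, 0.2, 0.5, NA, 1), c(0.1, 0.2, 0.55, 0.8, 1))
  labels <- cluster_screen(mat, k = 2)
  expect_true(same_partition(labels, c(1, 1, 2, 2)))
})
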