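test_that("per-profile reversal flags follow the strict sign rule", {
  sig <- disease_signature(up = c("u1", "u2", "u3"), down = c("d1",  "d2"))
  fc <- c(u1 = -0.3, u2 = 0.3, u3 = 0, d1 = 0.4, d2 = -0.4, other = 9)
  fl <- flag_reversals(fc, sig)
  expect_identical(nrow(fl), 5L)
  flags <- setNames(fl$reversed, fl$gene)
  expect_true(flags[["u1"]])    # disease-up pushed negative
  expect_false(flags[["u2"]])   # same sign as disease
  expect_false(flags[["u3"]])   # fc exactly 0 is not a reversal
  expect_true(flags[["d1"]])
  expect_false(flags[["d2"]])
})

test_that("class-level reversal uses the strict >60% rule", {
  sig <- disease_signature(up = "u1", down = "d1")
  make_prof <- function(n_rev) {
    fcs <- lapply(seq_len(10), function(i) {
      c(u1 = if (i <= n_rev) -1 else 1, d1 = -1, filler = 0.1)
    })
    profiles_tbl(fcs)
  }
  in7 <- class_reversal_genes(make_prof(7), sig)
  expect_true(in7$selected[in7$gene == "u1"])       # 0.7 > 0.6
  expect_equal(in7$reversal_fraction[in7$gene == "u1"], 0.7)
  out6 <- class_reversal_genes(make_prof(6), sig)
  expect_false(out6$selected[out6$gene == "u1"])    # 0.6 is not > 0.6
  all10 <- class_reversal_genes(make_prof(10), sig)
  expect_equal(all10$reversal_fraction[all10$gene == "u1"], 1)
  expect_true(all10$selected[all10$gene == "u1"])
})

test_that("exact Mann-Whitney p equals full enumeration for small groups", {
  # complete separation 3 vs 3: one-sided p = 3!3!/6! = 0.05 exactly
  expect_identical(mww_test(c(4, 5, 6), c(1, 2, 3), "greater")$p, 0.05)
  withr::with_seed(51, {
    for (i in 1:40) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      vals <- sample(1000, n1 + n2) / 7
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      alt <- sample(c("greater", "less"), 1)
      expect_equal(mww_test(x, y, alt, method = "exact")$p,
                   mww_exact_oracle(x, y, alt), tolerance = 1e-12)
    }
  })
})

test_that("swapping group labels flips the one-sided alternative", {
  withr::with_seed(52, {
    for (i in 1:20) {
      x <- runif(5); y <- runif(6)
      expect_equal(mww_test(x, y, "greater", method = "exact")$p,
                   mww_test(y, x, "less", method = "exact")$p,
                   tolerance = 1e-12)
    }
  })
})

test_that("identical rank distributions give p >= 0.5", {
  x <- c(0.1, 0.4, 0.7); y <- c(0.2, 0.5, 0.8)
  expect_gte(mww_test(x, y, "greater")$p, 0.5)
})

test_that("BH adjustment matches the step-up formula and a hand example", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.05, 0.05, 0.05, 0.05, 0.5))
  withr::with_seed(53, {
    p2 <- runif(25)
    expect_equal(p.adjust(p2, "BH"), bh_oracle(p2), tolerance = 1e-12)
  })
})

test_that("sensitive-vs-insensitive testing selects discriminating genes", {
  withr::with_seed(54, {
    n_genes <- 40
    genes <- sprintf("G%03d", seq_len(n_genes))
    sig <- disease_signature(up = genes[1:10], down = genes[11:20])
    # planted: u-genes G001,G002 reversed only in the sensitive group
    mk <- function(k, sensitive) {
      fcs <- lapply(seq_len(k), function(i) {
        fc <- rnorm(n_genes, 0, 0.3)
        names(fc) <- genes
        if (sensitive) fc[c("G001", "G002")] <- -abs(rnorm(2, 1.5, 0.2))
        fc
      })
      profiles_tbl(fcs, meta = tibble::tibble(
        drug = sprintf("d%02d", seq_len(k) + if (sensitive) 0 else 50),
        cell_line = "HL60", dose_uM = seq_len(k), time_h = 24))
    }
    res <- sensitive_vs_insensitive(mk(12, TRUE), mk(12, FALSE), sig)
    expect_true(all(res$selected[res$gene %in% c("G001", "G002")]))
    expect_true(all(res$fdr[res$tested] >= res$p[res$tested] - 1e-12))
    expect_lt(sum(res$selected), 10)  # null genes mostly unselected
  })
})

test_that("genes seen in fewer than 2 profiles per group are reported untested", {
  sig <- disease_signature(up = c("u1", "rare"), down = "d1")
  sens <- profiles_tbl(list(c(u1 = -1, d1 = 1, rare = -1),
                            c(u1 = -1, d1 = 1)))
  insens <- profiles_tbl(list(c(u1 = 1, d1 = -1), c(u1 = 1, d1 = -1)),
                         drug = "d9")
  res <- sensitive_vs_insensitive(sens, insens, sig)
  expect_false(res$tested[res$gene == "rare"])
  expect_true(all(res$tested[res$gene %in% c("u1", "d1")]))
})

test_that("class mean fold-change matrix aggregates drug means per class", {
  prof <- profiles_tbl(list(c(A = 1, B = 2), c(A = 3, B = 4)),
                       meta = tibble::tibble(drug = c("d1", "d2"),
                                             cell_line = "HL60",
                                             dose_uM = 1, time_h = 24))
  moa <- tibble::tibble(drug = c("d1", "d2"), moa_class = c("x", "x"))
  mat <- class_mean_fc_matrix(prof, moa, c("A", "B"))
  expect_equal(mat["A", "x"], 2)
  expect_equal(mat["B", "x"], 3)
})
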