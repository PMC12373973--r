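# Independent oracles, kept deliberately naive and separate from the
# package implementation paths they check.

# KS enrichment statistic by explicit loop over j for both running maxima.
ks_es_oracle <- function(V, n) {
  V <- sort(V)
  t <- length(V)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# One-sided Mann-Whitney p by full enumeration of all rank splits of the
# combined sample (tie-free data).
mww_exact_oracle <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">"))
  u_obs <- u_stat(x, y)
  comb <- c(x, y)
  n1 <- length(x)
  splits <- utils::combn(length(comb), n1)
  us <- apply(splits, 2, function(ix) u_stat(comb[ix], comb[-ix]))
  if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
}

# Benjamini-Hochberg step-up by the textbook formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Closed-form four-parameter logistic (restated independently).
fourpl_oracle <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) * ic50^hill / (ic50^hill + dose^hill)
}

# Welch two-sample one-tailed (x mean lower) t-test by formula.
welch_less_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  pt(tt, df)
}

# Do two label vectors define the same partition (adjusted Rand = 1)?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
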