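#' Kolmogorov-Smirnov enrichment statistic of a gene set in a ranked list
#'
#' Computes the unweighted connectivity-map form of the Kolmogorov-Smirnov
#' enrichment statistic for a query gene set occupying positions
#' \eqn{V(1) < \dots < V(t)} within a ranked list of \eqn{n} genes:
#' \deqn{a = \max_j \left( \frac{j}{t} - \frac{V(j)}{n} \right), \qquad
#'       b = \max_j \left( \frac{V(j)}{n} - \frac{j-1}{t} \right)}
#' and \eqn{es = a} if \eqn{a > b}, else \eqn{es = -b}. Positive values
#' indicate concentration of the set near the top of the ranking (rank 1),
#' negative values concentration near the bottom.
#'
#' @param positions Integer vector of distinct positions of the query set in
#'   the ranked list (1 = top). Order does not matter; positions are sorted
#'   internally.
#' @param n Size of the ranked universe.
#'
#' @return A list of class `"ks_es"` with elements `t` (set size), `n`,
#'   `positions` (sorted), `a`, `b`, and `es` in \eqn{[-1, 1]}.
#'
#' @examples
#' ks_es(1, n = 10)$es    #  0.9: single gene at the very top
#' ks_es(10, n = 10)$es   # -1.0: single gene at the very bottom
#' @export
ks_es <- function(positions, n) {
  if (!is_count(n) || n < 1) abort_config("`n` must be a positive integer")
  t <- length(positions)
  if (t == 0L) {
    abort_data("query set is empty; intersect the signature with the profile universe first")
  }
  positions <- sort(as.numeric(positions))
  if (anyDuplicated(positions) > 0L) {
    abort_data("`positions` must be distinct")
  }
  if (positions[1L] < 1 || positions[t] > n || any(positions != floor(positions))) {
    abort_data("`positions` must be integers within 1..n")
  }
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  es <- if (a > b) a else -b
  structure(list(t = t, n = n, positions = positions, a = a, b = b, es = es),
            class = "ks_es")
}

#' @export
print.ks_es <- function(x, ...) {
  cat(sprintf("<ks_es> t = %d, n = %d, a = %.4f, b = %.4f, es = %.4f\n",
              x$t, x$n, x$a, x$b, x$es))
  invisible(x)
}
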