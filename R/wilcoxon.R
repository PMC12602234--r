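# Paired Wilcoxon signed-rank test with an exact small-sample distribution.
# Zero differences are dropped (Wilcoxon's reduction), absolute differences
# are ranked with midranks for ties, and W+ is the sum of ranks of positive
# differences. For n_effective <= exact_cutoff the two-sided p-value comes
# from the exact null distribution over all 2^n sign assignments (computed
# by dynamic programming, which enumerates the same distribution without
# materialising the 2^n vectors); beyond the cutoff a normal approximation
# with tie and continuity corrections is used.

#' Paired Wilcoxon signed-rank test
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_cutoff Largest `n_effective` for which the exact distribution
#'   is used (default 25).
#' @return An object of class `wilcoxon_test`: list with `statistic` (W+, the
#'   sum of positive-difference ranks), `n_effective`, `p_value` (two-sided)
#'   and `mode` (`"exact"` or `"approximate"`).
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 1.5, 1.1), c(0.9, 0.7, 1.0, 1.2))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_cutoff = 25L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 1L) abort("Need at least one pair.")
  d <- x - y
  if (!all(is.finite(d))) abort("Differences must be finite.")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("All paired differences are zero: degenerate comparison.")
  r <- rank(abs(d))  # midranks for ties
  w_plus <- sum(r[d > 0])
  if (n <= exact_cutoff) {
    p <- wilcoxon_exact_p(r, w_plus)
    mode <- "exact"
  } else {
    p <- wilcoxon_approx_p(r, w_plus, n)
    mode <- "approximate"
  }
  structure(list(statistic = w_plus, n_effective = n, p_value = p, mode = mode),
            class = "wilcoxon_test")
}

# Exact two-sided p: 2 * min(P(W+ <= w), P(W+ >= w)) capped at 1, from the
# null distribution in which each rank enters the positive sum independently
# with probability 1/2. Midranks are multiples of 1/2, so doubling makes all
# rank contributions integer and the distribution is computed by polynomial
# convolution over achievable doubled sums.
wilcoxon_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with sum s
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  n_assign <- 2^length(ranks)
  w2 <- round(2 * w_plus)
  p_le <- sum(counts[seq_len(w2 + 1L)]) / n_assign
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / n_assign
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
wilcoxon_approx_p <- function(ranks, w_plus, n) {
  mu <- n * (n + 1) / 4
  tie_tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(1)
  cc <- if (w_plus > mu) -0.5 else if (w_plus < mu) 0.5 else 0
  z <- (w_plus - mu + cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.wilcoxon_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s): W+ = %g, n = %d, p = %.4g\n",
              x$mode, x$statistic, x$n_effective, x$p_value))
  invisible(x)
}
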