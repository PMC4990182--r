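#' Storey q-values
#'
#' Estimates the null proportion pi0 from `pi0(lambda) = #[p > lambda] /
#' (m (1 - lambda))` over `lambda = 0.05, 0.10, ..., 0.95`, smoothed by a
#' natural cubic smoothing spline with 3 degrees of freedom and evaluated at
#' `lambda = 0.95` (capped into (0, 1]). Q-values are the cumulative minimum
#' from the largest p of `pi0 * m * p_(i) / i`. For fewer than `min_m`
#' p-values the smoother is unstable and pi0 defaults to 1, which reduces
#' the procedure to Benjamini-Hochberg.
#'
#' @param p_values P-values in (0, 1].
#' @param pi0 Optional fixed pi0 (bypasses estimation).
#' @param min_m Minimum number of tests for pi0 estimation (default 100).
#' @return Q-values in the input order.
#' @export
qvalue_estimate <- function(p_values, pi0 = NULL, min_m = 100L) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  assert_prob(p_values, "p-values")
  if (is.null(pi0)) {
    pi0 <- if (m < min_m) 1 else estimate_pi0(p_values)
  }
  stopifnot(pi0 > 0, pi0 <= 1)
  ord <- order(p_values, decreasing = TRUE)
  # descending scan: element j of the sorted vector has ascending rank m-j+1
  q <- pi0 * m * p_values[ord] / seq(m, 1)
  q <- pmin(cummin(pmin(q, 1)), 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = 0.95)$y
  min(max(pi0, 1e-8), 1)
}
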