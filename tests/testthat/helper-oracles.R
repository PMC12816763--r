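# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Brute-force monoexponential fit: dense grid over k with the (asymptote,
# amplitude) pair profiled out by linear least squares at each k, followed
# by one local grid refinement. Weighted to match the estimator's objective
# when w is supplied.
grid_search_recovery <- function(t, y, w = NULL,
                                 k_grid = seq(0.05, 10, by = 0.002)) {
  if (is.null(w)) w <- rep(1, length(y))
  sse_at <- function(k) {
    e <- exp(-(k / 60) * t)
    fit <- stats::lm(y ~ e, weights = w)
    cf <- stats::coef(fit)
    if (cf[2] < 0 || cf[1] < 0) {
      # enforce the sign constraints by bounded refit
      a <- max(0, cf[1])
      amp <- max(0, cf[2])
      return(sum(w * (y - a - amp * e)^2))
    }
    sum(w * stats::resid(fit)^2)
  }
  sse <- vapply(k_grid, sse_at, numeric(1))
  k0 <- k_grid[which.min(sse)]
  fine <- seq(max(1e-4, k0 - 0.002), k0 + 0.002, length.out = 401)
  sse_f <- vapply(fine, sse_at, numeric(1))
  k_hat <- fine[which.min(sse_f)]
  e <- exp(-(k_hat / 60) * t)
  cf <- stats::coef(stats::lm(y ~ e, weights = w))
  list(k = k_hat, asymptote = unname(cf[1]), amplitude = unname(cf[2]),
       ssr = min(sse_f))
}

# Exact two-sided Fisher p for a 2x2 table by full hypergeometric
# enumeration (probability-ordering definition).
enumerate_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_vals, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Synthetic mVO2 recovery points lying exactly on the generating
# exponential (t in seconds, k in min^-1).
exact_recovery_points <- function(k, amplitude = 0.33, asymptote = 0.02,
                                  t = c(seq(5, 60, by = 12),
                                        seq(75, 240, by = 18))) {
  data.frame(t = t, value = asymptote + amplitude * exp(-(k / 60) * t),
             usable = TRUE)
}
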