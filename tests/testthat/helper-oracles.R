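# Independent oracles and shared fixtures for the test suite.

# Vectorised bisection for the roots of tan(q) = -alpha*q in
# ((k-1/2)pi, k*pi). Pure bisection, independent of the package's
# Brent-based solver; 90 halvings of a pi-wide bracket reach the double
# resolution limit.
bisect_roots <- function(alpha, n, iters = 90L) {
  k <- seq_len(n)
  lo <- (k - 0.5) * pi + 1e-9
  hi <- k * pi - 1e-9
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- tan(mid) + alpha * mid > 0     # f rises from -Inf to f(hi) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

# geometry used throughout: 100 um film, both faces exposed (L = 50 um)
test_geometry <- function(V_simulant = 2e-9) {
  release_geometry(1e-4, V_film = 2e-7, V_simulant = V_simulant)
}

# dimensionless comparison grid spanning 0 to 5 L^2/D, dense at early times
oracle_time_grid <- function(L, D, n = 60) {
  c(0, exp(seq(log(1e-4 * L^2 / D), log(5 * L^2 / D), length.out = n)))
}
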