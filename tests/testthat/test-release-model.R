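test_that("alpha follows V_S / (K_FS * V_F) and rejects bad input", {
  expect_equal(compute_alpha(1, 1, 1), 1)
  expect_equal(compute_alpha(4, 1, 2), 2)
  # desk evaluation: 2e-4 / (0.681 * 2e-8)
  expect_equal(compute_alpha(2e-4, 2e-8, 0.681), 1.4684e4, tolerance = 1e-4)
  expect_error(compute_alpha(-1, 1, 1), "V_S")
  expect_error(compute_alpha(1, 0, 1), "V_F")
  expect_error(compute_alpha(1, 1, -2), "K_FS")

  g <- test_geometry()
  expect_equal(alpha_from_geometry(g, 0.681), 2e-9 / (0.681 * 2e-7))
})

test_that("partition coefficient is the equilibrium concentration ratio", {
  expect_equal(partition_coefficient(0.681, 1), 0.681)
  expect_equal(partition_coefficient(0, 1), 0)
  expect_equal(partition_coefficient(5, 5), 1)
  expect_error(partition_coefficient(1, 0), "C_S_inf")
})

test_that("geometry maps measured thickness to the characteristic length", {
  expect_equal(release_geometry(1e-4, 1e-7, 1e-7)$L, 5e-5)
  expect_equal(release_geometry(1e-4, 1e-7, 1e-7, "one_sided")$L, 1e-4)
  expect_error(release_geometry(0, 1, 1), "thickness")
})

test_that("eigenvalue roots match an independent bisection and their limits", {
  # first root for alpha = 1, frozen from 90-step bisection of tan(q) + q
  rs <- find_roots(1)
  expect_equal(rs$roots[1], 2.02875783811043, tolerance = 1e-12)
  expect_equal(rs$n_roots, 12L)
  expect_true(all(diff(rs$roots) > 0))

  # alpha -> 0+: roots approach k*pi; alpha -> Inf: (2k-1)*pi/2
  k <- 1:12
  expect_equal(find_roots(1e-9)$roots, k * pi, tolerance = 1e-6)
  expect_equal(find_roots(1e9)$roots, (2 * k - 1) * pi / 2, tolerance = 1e-6)

  # random alphas: agreement with bisection, brackets, pole-safe residuals
  set.seed(7)
  for (a in 10^stats::runif(40, -4, 4)) {
    rs <- find_roots(a)
    expect_equal(rs$roots, bisect_roots(a, 12), tolerance = 1e-10)
    expect_true(all(rs$roots > (k - 0.5) * pi & rs$roots < k * pi))
    expect_lt(max(root_residuals(rs)), 1e-10)
  }
})

test_that("series weights sum toward 1 and the truncation bound is honest", {
  # deficit shrinks as prescribed by series_roots_needed
  for (a in c(0.05, 0.5, 5)) {
    n <- series_roots_needed(a, 1e-3)
    deficit <- 1 - sum(series_weights(find_roots(a, n)))
    expect_lt(deficit, 1.2e-3)
    expect_gt(deficit, 0)
  }
  # at the conventional 12 roots the deficit is small only for alpha >~ 0.5;
  # at the low-alpha end of the series regime it is large -- the reason the
  # erfc model takes over below alpha = 0.01
  expect_lt(1 - sum(series_weights(find_roots(1))), 0.05)
  expect_lt(1 - sum(series_weights(find_roots(50))), 0.05)
  expect_gt(1 - sum(series_weights(find_roots(0.01))), 0.5)
})

test_that("series release runs from its truncation offset at t = 0 to 1", {
  g <- test_geometry()
  a <- 1
  rts <- find_roots(a)
  v0 <- fractional_release_series(0, 1e-13, g, a, roots = rts)
  expect_equal(as.numeric(v0), 1 - sum(series_weights(rts)))
  expect_lt(as.numeric(v0), 0.05)                       # near 0 at t = 0
  expect_equal(
    as.numeric(fractional_release_series(1e15, 1e-13, g, a, roots = rts)), 1)

  # clamping keeps [0, 1] and preserves the raw values
  v <- fractional_release_series(c(0, 1e3, 1e5), 1e-13, g, a, roots = rts)
  expect_true(all(v >= 0 & v <= 1))
  expect_length(attr(v, "raw"), 3)
})

test_that("series and erfc releases are non-decreasing in t and in D", {
  g <- test_geometry()
  t <- c(0, 10^seq(1, 6, by = 0.25))
  for (a in c(0.05, 1, 50)) {
    rts <- find_roots(a)
    expect_true(all(diff(fractional_release_series(t, 1e-13, g, a,
                                                   roots = rts)) >= 0))
    for (tt in c(1e3, 1e5)) {
      by_D <- vapply(10^seq(-16, -11, by = 0.5), function(D)
        as.numeric(fractional_release_series(tt, D, g, a, roots = rts)),
        numeric(1))
      expect_true(all(diff(by_D) >= 0))
    }
  }
  a <- 0.005
  expect_true(all(diff(as.numeric(
    fractional_release_erfc(t, 1e-14, g, a, warn = FALSE))) >= 0))
  by_D <- vapply(10^seq(-16, -11, by = 0.5), function(D)
    as.numeric(fractional_release_erfc(1e3, D, g, a, warn = FALSE)),
    numeric(1))
  expect_true(all(diff(by_D) >= 0))
})

test_that("erfc model is exact at t = 0, stable and flagged at large omega", {
  g <- test_geometry()
  v <- fractional_release_erfc(0, 1e-14, g, 0.005, warn = FALSE)
  expect_identical(as.numeric(v), 0)

  # omega ~ 1e10: naive exp(omega)*erfc overflows; result must approach
  # the (1 + alpha) asymptote and be flagged as exceeding 1
  big <- fractional_release_erfc(1e12, 1e-13, g, 0.005, warn = FALSE)
  expect_true(is.finite(big))
  expect_equal(as.numeric(big), 1.005, tolerance = 1e-4)
  expect_true(attr(big, "exceeds_unity"))
  expect_warning(fractional_release_erfc(1e12, 1e-13, g, 0.005), "exceed")
})

test_that("erfc and a truncation-controlled series agree at low alpha", {
  # short-time window (release <= 0.1) where both forms describe the same
  # physics; the series needs its order set from the truncation bound
  g <- test_geometry()
  a <- 0.02
  D <- 1e-14
  rts <- find_roots(a, series_roots_needed(a, 5e-4))
  omega <- seq(1e-4, 0.0078, length.out = 15)
  t <- omega * a^2 * g$L^2 / D
  s <- fractional_release_series(t, D, g, a, roots = rts)
  e <- fractional_release_erfc(t, D, g, a, warn = FALSE)
  expect_lt(max(s), 0.11)
  expect_lt(max(abs(as.numeric(s) - as.numeric(e))), 1e-3)
})

test_that("model selection follows the alpha = 0.01 rule", {
  expect_identical(select_model(0.0147), "series")
  expect_identical(select_model(7.34e-4), "erfc")
  expect_identical(select_model(0.01), "series")   # boundary inclusive
  expect_warning(out <- select_model(2000), "validated range")
  expect_identical(out, "series")
})

test_that("mismatched root sets are rejected", {
  g <- test_geometry()
  rts <- find_roots(0.5)
  expect_error(fractional_release_series(1e3, 1e-13, g, 0.7, roots = rts),
               "alpha")
})
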