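test_that("release curves validate their inputs", {
  expect_error(release_curve(c(0, 1, 2), c(0, 1, 2)), "at least 4")
  expect_error(release_curve(c(0, 1, 1, 2), c(0, 1, 2, 3)), "duplicate")
  expect_error(release_curve(c(0, 2, 1, 3), c(0, 1, 2, 3)), "increasing")
  expect_error(release_curve(c(0, 1, 2, 3), c(0, -1, 2, 3)), ">= 0")
  cur <- release_curve(c(0, 3, 6, 9), c(0, 5, 8, 9), time_unit = "h")
  expect_equal(cur$time_s, c(0, 3, 6, 9) * 3600)
})

test_that("equilibrium extraction averages the plateau or passes through", {
  cur <- release_curve(1:6, c(0, 5, 9, 10, 10, 10))
  expect_equal(estimate_equilibrium(cur), 10)
  cur2 <- release_curve(1:6, c(0, 5, 9, 10, 11, 9))
  expect_equal(estimate_equilibrium(cur2), 10)
  cur3 <- release_curve(1:6, c(0, 5, 9, 10, 11, 9), C_S_inf = 7.5)
  expect_equal(estimate_equilibrium(cur3), 7.5)
  expect_error(estimate_equilibrium(cur, plateau_points = 9), "between")
})

test_that("R^2 follows 1 - SS_res/SS_tot", {
  expect_equal(r_squared(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  obs <- c(1, 2, 3, 6)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "identical")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("noiseless synthetic curves return the generating D exactly", {
  for (sc in release_scenarios()) {
    cur <- generate_release_curve(sc, noise_cv = 0)
    fit <- fit_diffusion(cur, scenario_geometry(sc), alpha = sc$alpha_true)
    expect_lt(abs(log10(fit$D_hat / sc$D_true)), 0.005)
    expect_gt(fit$r_squared, 0.999)
    expect_true(fit$converged)
    expect_identical(fit$model_used, select_model(sc$alpha_true))
  }
})

test_that("the fit is invariant to the concentration scale", {
  sc <- release_scenarios()[["fatty_4C"]]
  base <- generate_release_curve(sc, noise_cv = 0)
  for (scale in c(0.037, 1, 812)) {
    cur <- release_curve(base$time_s, base$concentration * scale)
    fit <- fit_diffusion(cur, sc$L, alpha = sc$alpha_true)
    ref <- fit_diffusion(release_curve(base$time_s, base$concentration),
                         sc$L, alpha = sc$alpha_true)
    expect_equal(fit$D_hat, ref$D_hat, tolerance = 1e-12)
  }
})

test_that("fitting is deterministic", {
  sc <- release_scenarios()[["hydrophilic_24C"]]
  cur <- generate_release_curve(sc, seed = 11)
  f1 <- fit_diffusion(cur, scenario_geometry(sc), alpha = sc$alpha_true)
  f2 <- fit_diffusion(cur, scenario_geometry(sc), alpha = sc$alpha_true)
  expect_identical(f1, f2)
})

test_that("alpha provenance is explicit and degenerate input rejected", {
  sc <- release_scenarios()[["fatty_4C"]]
  cur <- generate_release_curve(sc, noise_cv = 0)
  g <- scenario_geometry(sc)
  expect_error(fit_diffusion(cur, g), "exactly one")
  expect_error(fit_diffusion(cur, g, K_FS = 0.681, alpha = 0.0147),
               "exactly one")
  # K_FS route and alpha route agree (geometry was built from alpha*K_FS)
  f1 <- fit_diffusion(cur, g, K_FS = sc$K_FS_true)
  f2 <- fit_diffusion(cur, g, alpha = sc$alpha_true)
  expect_equal(f1$D_hat, f2$D_hat, tolerance = 1e-6)

  zero <- release_curve(c(0, 1, 2, 3), rep(0, 4))
  expect_error(fit_diffusion(zero, g, alpha = 0.5), "no release")
})

test_that("joint (D, alpha) estimation recovers both on an informative curve", {
  sc <- release_scenario("joint", "fatty", 24, D_true = 1e-13,
                         alpha_true = 0.5, K_FS_true = 1)
  cur <- generate_release_curve(sc, schedule = seq(0, 48, 2) * 3600,
                                noise_cv = 0)
  fit <- fit_diffusion(cur, sc$L, alpha = 1, estimate_alpha = TRUE)
  expect_equal(fit$D_hat, 1e-13, tolerance = 0.02)
  expect_equal(fit$alpha_used, 0.5, tolerance = 0.02)
})

test_that("C_t/C_0 bookkeeping reproduces the scenario targets", {
  for (nm in c("fatty_4C", "fatty_24C")) {
    sc <- release_scenarios()[[nm]]
    cur <- generate_release_curve(sc, noise_cv = 0)
    ratio <- ct_over_c0(cur)
    expect_equal(max(ratio), sc$ct_c0_target, tolerance = 1e-6)
  }
  # all-zero concentrations give all-zero ratios
  zc <- release_curve(c(0, 1, 2, 3), rep(0, 4), C0_film = 5,
                      simulant_mass = 1e-3)
  expect_identical(as.numeric(ct_over_c0(zc)), rep(0, 4))
  # complete release: final ratio 1
  cc <- release_curve(c(0, 1, 2, 3), c(0, 2, 4, 5), C0_film = 5e-3,
                      simulant_mass = 1e-3)
  expect_equal(max(ct_over_c0(cc)), 1)
  expect_error(ct_over_c0(release_curve(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               "C0_film")
})
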