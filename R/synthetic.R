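#' Define a synthetic release scenario
#'
#' A scenario bundles the physical truth (D, alpha, K_FS, geometry) with
#' the sampling design and noise model used to simulate a release
#' experiment. The four study presets are available from
#' [release_scenarios()].
#'
#' Volumes are chosen to be internally consistent with `alpha_true` and
#' `K_FS_true`: `V_S = alpha * K_FS * V_F` with `V_F = 2e-7` m^3 (a 0.2 g
#' film at unit density). The absolute scale of the volumes never enters
#' the release models -- only `alpha` does.
#'
#' @param name Scenario label.
#' @param simulant `"fatty"` or `"hydrophilic"`.
#' @param temperature Temperature label in degrees C.
#' @param D_true True diffusion coefficient, m^2/s.
#' @param alpha_true True volume ratio.
#' @param K_FS_true True partition coefficient.
#' @param L Characteristic half-thickness in metres (default 5e-5, i.e. a
#'   100 um solvent-cast film released from both faces).
#' @param C_S_inf Equilibrium simulant concentration, mg GAE/kg
#'   (default 100; fits are scale invariant).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (default 0.05).
#' @param n_replicates Default number of replicate films (default 3).
#' @param ct_c0_target Optional target for the final released fraction of
#'   the initial film content; used to back out `C0_film`.
#' @return An object of class `release_scenario`.
#' @export
release_scenario <- function(name, simulant, temperature, D_true, alpha_true,
                             K_FS_true, L = 5e-5, C_S_inf = 100,
                             noise_cv = 0.05, n_replicates = 3L,
                             ct_c0_target = NA_real_) {
  .check_positive(D_true = D_true, alpha_true = alpha_true,
                  K_FS_true = K_FS_true, L = L, C_S_inf = C_S_inf)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  stopifnot(simulant %in% c("fatty", "hydrophilic"))
  structure(
    list(name = name, simulant = simulant, temperature = temperature,
         D_true = D_true, alpha_true = alpha_true, K_FS_true = K_FS_true,
         L = L, C_S_inf = C_S_inf, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates),
         ct_c0_target = ct_c0_target),
    class = "release_scenario")
}

#' @export
print.release_scenario <- function(x, ...) {
  cat(sprintf("Release scenario '%s': %s simulant, %s degC\n",
              x$name, x$simulant, x$temperature))
  cat(sprintf("  D = %.4g x 10^-14 m^2/s, alpha = %.4g, K_FS = %.4g\n",
              x$D_true * 1e14, x$alpha_true, x$K_FS_true))
  cat(sprintf("  L = %g m, C_S_inf = %g mg GAE/kg, noise CV = %g\n",
              x$L, x$C_S_inf, x$noise_cv))
  invisible(x)
}

#' Geometry implied by a scenario
#'
#' Builds the [release_geometry()] consistent with the scenario's `L`,
#' `alpha_true` and `K_FS_true` (two-sided exposure, film volume 2e-7 m^3).
#'
#' @param scenario A [release_scenario()].
#' @return A `release_geometry`.
#' @export
scenario_geometry <- function(scenario) {
  stopifnot(inherits(scenario, "release_scenario"))
  V_F <- 2e-7
  release_geometry(thickness = 2 * scenario$L, V_film = V_F,
                   V_simulant = scenario$alpha_true * scenario$K_FS_true * V_F,
                   exposure = "two_sided")
}

#' The four study scenario presets
#'
#' Fatty (95% ethanol) and hydrophilic (10% ethanol) food simulants at 4
#' and 24 degrees C, carrying the reported release parameters: D of 5.115,
#' 21.140, 0.802 and 5.949 (x 10^-14 m^2/s), alpha of 0.0147, 0.0181,
#' 7.34e-4 and 9.19e-4, and K_FS of 0.681, 0.552, 13.630 and 10.880
#' respectively. Final `C_t/C_0` targets are 0.595, 0.644, 0.0684 and
#' 0.0893. In all four presets `alpha * K_FS = 0.01`, i.e. the implied
#' simulant/film volume ratio is identical across conditions.
#'
#' @return Named list of four [release_scenario()] objects:
#'   `fatty_4C`, `fatty_24C`, `hydrophilic_4C`, `hydrophilic_24C`.
#' @examples
#' names(release_scenarios())
#' @export
release_scenarios <- function() {
  list(
    fatty_4C = release_scenario("fatty_4C", "fatty", 4,
      D_true = 5.115e-14, alpha_true = 0.0147, K_FS_true = 0.681,
      ct_c0_target = 0.595),
    fatty_24C = release_scenario("fatty_24C", "fatty", 24,
      D_true = 21.140e-14, alpha_true = 0.0181, K_FS_true = 0.552,
      ct_c0_target = 0.644),
    hydrophilic_4C = release_scenario("hydrophilic_4C", "hydrophilic", 4,
      D_true = 0.802e-14, alpha_true = 7.34e-4, K_FS_true = 13.630,
      ct_c0_target = 0.0684),
    hydrophilic_24C = release_scenario("hydrophilic_24C", "hydrophilic", 24,
      D_true = 5.949e-14, alpha_true = 9.19e-4, K_FS_true = 10.880,
      ct_c0_target = 0.0893)
  )
}

#' Sampling schedule of the release study
#'
#' Sampling every 3 h over the first 24 h, then every 24 h for the
#' following 3 days: 0, 3, 6, ..., 24, 48, 72, 96 h (12 timepoints).
#'
#' @param unit `"s"` (default) or `"h"`.
#' @return Numeric vector of sampling times.
#' @examples
#' release_sampling_schedule("h")
#' @export
release_sampling_schedule <- function(unit = c("s", "h")) {
  unit <- match.arg(unit)
  hours <- c(seq(0, 24, by = 3), 48, 72, 96)
  if (unit == "h") hours else hours * 3600
}

#' Simulate one release curve
#'
#' Evaluates the forward model selected by the scenario's `alpha_true`
#' (series for `alpha >= 0.01`, erfc below) at the schedule times, scales
#' by the equilibrium concentration `C_S_inf`, and applies multiplicative
#' Gaussian noise `c * (1 + eps)`, `eps ~ N(0, noise_cv)`, truncated at
#' zero. The returned curve carries the known `C_S_inf`, the film's initial
#' content `C0_film` (when the scenario has a `C_t/C_0` target) and the
#' simulant mass, so downstream normalisation and mass bookkeeping are
#' exact.
#'
#' @param scenario A [release_scenario()].
#' @param schedule Sampling times in seconds (default
#'   [release_sampling_schedule()]).
#' @param seed Optional integer seed for reproducibility.
#' @param noise_cv Override of the scenario's noise level.
#' @param replicate Replicate label stored on the curve.
#' @param n_roots Series order for the forward model (default 12).
#' @return A [release_curve()].
#' @export
generate_release_curve <- function(scenario,
                                   schedule = release_sampling_schedule(),
                                   seed = NULL, noise_cv = scenario$noise_cv,
                                   replicate = NA, n_roots = 12L) {
  stopifnot(inherits(scenario, "release_scenario"))
  if (!is.null(seed)) set.seed(seed)
  ratio <- fractional_release(schedule, scenario$D_true, scenario$L,
                              scenario$alpha_true, n_roots = n_roots,
                              warn = FALSE)
  conc <- scenario$C_S_inf * as.numeric(ratio)
  if (noise_cv > 0)
    conc <- pmax(0, conc * (1 + stats::rnorm(length(conc), sd = noise_cv)))

  geom <- scenario_geometry(scenario)
  sim_mass <- geom$V_simulant * 1000          # kg, at ~1000 kg/m^3
  C0 <- if (is.finite(scenario$ct_c0_target))
    scenario$C_S_inf * sim_mass / scenario$ct_c0_target else NULL

  release_curve(schedule, conc, time_unit = "s",
                simulant = scenario$simulant,
                temperature = scenario$temperature,
                replicate = replicate,
                C_S_inf = scenario$C_S_inf,
                C0_film = C0, simulant_mass = sim_mass)
}

#' Simulate the full release study
#'
#' All four presets (fatty/hydrophilic x 4/24 degC), `n_replicates` curves
#' each, every curve drawn with a distinct sub-seed derived from `seed`.
#'
#' @param seed Integer master seed.
#' @param scenarios List of [release_scenario()] objects (default the four
#'   presets).
#' @param n_replicates Replicates per scenario; default each scenario's own
#'   setting.
#' @param noise_cv Optional noise override applied to every scenario.
#' @param schedule Sampling times in seconds.
#' @return A list of [release_curve()] objects with a `"seeds"` attribute
#'   recording the per-curve sub-seeds.
#' @examples
#' curves <- generate_study(seed = 1)
#' length(curves)  # 12
#' @export
generate_study <- function(seed, scenarios = release_scenarios(),
                           n_replicates = NULL, noise_cv = NULL,
                           schedule = release_sampling_schedule()) {
  set.seed(seed)
  reps <- vapply(scenarios, function(s)
    if (is.null(n_replicates)) s$n_replicates else as.integer(n_replicates),
    integer(1))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, sum(reps))
  curves <- vector("list", sum(reps))
  nm <- character(sum(reps))
  i <- 0L
  for (s_idx in seq_along(scenarios)) {
    sc <- scenarios[[s_idx]]
    for (r in seq_len(reps[s_idx])) {
      i <- i + 1L
      curves[[i]] <- generate_release_curve(
        sc, schedule = schedule, seed = sub_seeds[i],
        noise_cv = if (is.null(noise_cv)) sc$noise_cv else noise_cv,
        replicate = r)
      nm[i] <- sprintf("%s_rep%d", sc$name, r)
    }
  }
  names(curves) <- nm
  attr(curves, "seeds") <- stats::setNames(sub_seeds, nm)
  attr(curves, "master_seed") <- seed
  curves
}
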