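#' Transport geometry of a plane-sheet film in a finite bath
#'
#' Bundles the measured film thickness, the film and simulant volumes, and
#' the exposure convention into the characteristic diffusion length `L` that
#' enters the release models through `exp(-D q_n^2 t / L^2)`.
#'
#' For a film immersed in the simulant with both faces exposed
#' (`exposure = "two_sided"`, the default) the concentration profile is
#' symmetric about the midplane and `L` is half the measured thickness; for a
#' film released from one face only (e.g. laminated on a backing)
#' `L` equals the full measured thickness.
#'
#' @param thickness Measured film thickness in metres (> 0).
#' @param V_film Film volume in cubic metres (> 0).
#' @param V_simulant Simulant volume in cubic metres (> 0).
#' @param exposure `"two_sided"` (default) or `"one_sided"`.
#'
#' @return An object of class `release_geometry` with elements `L`
#'   (characteristic length, m), `thickness`, `V_film`, `V_simulant`,
#'   `exposure`.
#' @examples
#' geom <- release_geometry(1e-4, V_film = 2e-7, V_simulant = 2e-9)
#' geom$L  # 5e-5: half the measured thickness
#' @seealso [compute_alpha()], [fractional_release_series()]
#' @export
release_geometry <- function(thickness, V_film, V_simulant,
                             exposure = c("two_sided", "one_sided")) {
  exposure <- match.arg(exposure)
  .check_positive(thickness = thickness, V_film = V_film,
                  V_simulant = V_simulant)
  L <- if (exposure == "two_sided") thickness / 2 else thickness
  structure(
    list(L = L, thickness = thickness, V_film = V_film,
         V_simulant = V_simulant, exposure = exposure),
    class = "release_geometry"
  )
}

#' @export
print.release_geometry <- function(x, ...) {
  cat("Plane-sheet release geometry\n")
  cat(sprintf("  thickness : %g m (%s exposure -> L = %g m)\n",
              x$thickness, x$exposure, x$L))
  cat(sprintf("  V_film    : %g m^3\n", x$V_film))
  cat(sprintf("  V_simulant: %g m^3\n", x$V_simulant))
  invisible(x)
}

#' Volume ratio alpha of the limited-volume release problem
#'
#' `alpha = V_S / (K_FS * V_F)` relates the simulant volume to the film
#' volume scaled by the film/simulant partition coefficient. It controls the
#' finite-bath equilibrium (the fraction `alpha / (1 + alpha)` of the
#' initial load is eventually released) and enters the eigenvalue condition
#' `tan(q) = -alpha * q`.
#'
#' @param V_S Simulant volume (m^3, > 0).
#' @param V_F Film volume (m^3, > 0).
#' @param K_FS Dimensionless film/simulant partition coefficient (> 0).
#' @return Dimensionless `alpha`.
#' @examples
#' compute_alpha(V_S = 4, V_F = 1, K_FS = 2)  # 2
#' @export
compute_alpha <- function(V_S, V_F, K_FS) {
  .check_positive(V_S = V_S, V_F = V_F, K_FS = K_FS)
  V_S / (K_FS * V_F)
}

#' @describeIn compute_alpha Derive `alpha` from a [release_geometry()].
#' @param geometry A `release_geometry` object.
#' @export
alpha_from_geometry <- function(geometry, K_FS) {
  stopifnot(inherits(geometry, "release_geometry"))
  compute_alpha(geometry$V_simulant, geometry$V_film, K_FS)
}

#' Film/simulant partition coefficient at equilibrium
#'
#' `K_FS = C_F_inf / C_S_inf`: the ratio of the antioxidant concentration
#' remaining in the film to that in the simulant once release has
#' equilibrated. Small values mean the compound strongly prefers the
#' simulant (near-complete release).
#'
#' @param C_F_inf Equilibrium concentration in the film (>= 0).
#' @param C_S_inf Equilibrium concentration in the simulant (> 0); both in
#'   the same units.
#' @return Dimensionless `K_FS`.
#' @examples
#' partition_coefficient(0.681, 1)  # 0.681
#' @export
partition_coefficient <- function(C_F_inf, C_S_inf) {
  if (any(!is.finite(C_S_inf)) || any(C_S_inf <= 0))
    stop("C_S_inf must be > 0: a zero equilibrium simulant concentration ",
         "means no release occurred and K_FS is undefined", call. = FALSE)
  if (any(!is.finite(C_F_inf)) || any(C_F_inf < 0))
    stop("C_F_inf must be >= 0", call. = FALSE)
  C_F_inf / C_S_inf
}

# shared scalar-positivity check; names the offending argument
.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("'%s' must be a positive finite number", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}
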