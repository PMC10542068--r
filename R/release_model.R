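#' Series weights of the limited-volume plane-sheet solution
#'
#' Weight of the n-th eigenmode,
#' `2 alpha (1 + alpha) / (1 + alpha + alpha^2 q_n^2)`. Over the infinite
#' root set the weights sum to 1 (so the fractional release is 0 at `t = 0`
#' and 1 at equilibrium); a truncated sum falls short by the truncation
#' deficit quantified in [series_roots_needed()].
#'
#' @param roots A `root_set` from [find_roots()].
#' @return Numeric vector of per-mode weights.
#' @export
series_weights <- function(roots) {
  stopifnot(inherits(roots, "root_set"))
  a <- roots$alpha
  q <- roots$roots
  2 * a * (1 + a) / (1 + a + a^2 * q^2)
}

# scaled complementary error function exp(x^2) erfc(x), robust for large x.
# pracma::erfcx evaluates the product naively and returns NaN once erfc
# underflows (x >~ 26); switch there to the asymptotic expansion
# erfcx(x) ~ (1 - s + 3s^2 - 15s^3 + ...) / (x sqrt(pi)), s = 1/(2x^2),
# whose truncation error at x = 25 is already ~1e-13 relative.
.erfcx <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xl <- x[!small]
    s <- 1 / (2 * xl^2)
    out[!small] <- (1 - s * (1 - s * (3 - s * (15 - 105 * s)))) /
      (xl * sqrt(pi))
  }
  out
}

# resolve a geometry argument to a characteristic length L (metres)
.resolve_L <- function(geometry) {
  if (inherits(geometry, "release_geometry")) return(geometry$L)
  if (is.numeric(geometry) && length(geometry) == 1L && is.finite(geometry) &&
      geometry > 0)
    return(geometry)
  stop("'geometry' must be a release_geometry object or a single positive ",
       "characteristic length in metres", call. = FALSE)
}

#' Fractional release: limited-volume eigenfunction series
#'
#' Fraction of the equilibrium simulant concentration reached at time `t`
#' for diffusion out of a plane sheet into a finite, well-stirred bath:
#' \deqn{C_{S,t}/C_{S,\infty} = 1 - \sum_{n=1}^{N}
#'   \frac{2\alpha(1+\alpha)}{1+\alpha+\alpha^2 q_n^2}
#'   \exp\!\left(-\frac{D q_n^2 t}{L^2}\right)}
#' with `q_n` the roots of `tan(q) = -alpha q`.
#'
#' The truncated sum is clamped to `[0, 1]`; the raw pre-clamp values are
#' kept in the `"raw"` attribute. Truncation leaves a spurious positive
#' offset at `t = 0` equal to the missing weight (negligible for
#' `alpha >~ 0.5` at the default 12 roots, large for small `alpha`; see
#' [series_roots_needed()]).
#'
#' @param t Time(s) in seconds (>= 0); vectorised.
#' @param D Diffusion coefficient in m^2/s (> 0).
#' @param geometry A [release_geometry()] or a single characteristic length
#'   `L` in metres.
#' @param alpha Dimensionless volume ratio (> 0).
#' @param roots Optional precomputed `root_set` for this `alpha`; must match
#'   `alpha` or an error is raised.
#' @param n_roots Number of roots if `roots` is not supplied (default 12).
#' @param clamp Clamp to `[0, 1]` (default `TRUE`).
#' @return Numeric vector of fractional release values, with attribute
#'   `"raw"` holding the pre-clamp series values.
#' @examples
#' g <- release_geometry(1e-4, 2e-7, 1e-7)
#' fractional_release_series(c(0, 3600, 36000), D = 1e-13, g, alpha = 0.5)
#' @export
fractional_release_series <- function(t, D, geometry, alpha, roots = NULL,
                                      n_roots = 12L, clamp = TRUE) {
  .check_positive(D = D, alpha = alpha)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0 (seconds)", call. = FALSE)
  L <- .resolve_L(geometry)
  if (is.null(roots)) {
    roots <- find_roots(alpha, n_roots)
  } else {
    stopifnot(inherits(roots, "root_set"))
    if (abs(roots$alpha - alpha) > 1e-12 * max(1, alpha))
      stop(sprintf(
        "root set was computed for alpha = %g but alpha = %g was supplied",
        roots$alpha, alpha), call. = FALSE)
  }
  w <- series_weights(roots)
  lam <- D * roots$roots^2 / L^2          # per-mode decay rates, 1/s
  # exp(-lam %o% t): modes x times; colSums gives the remaining sum
  raw <- 1 - as.vector(crossprod(exp(-outer(lam, t)), w))
  out <- if (clamp) pmin(pmax(raw, 0), 1) else raw
  attr(out, "raw") <- raw
  out
}

#' Fractional release: short-time complementary-error-function model
#'
#' Low-migration alternative to the eigenfunction series, used when
#' `alpha < 0.01` where the series needs impractically many roots:
#' \deqn{C_{S,t}/C_{S,\infty} = (1+\alpha)\left[1 -
#'   e^{\omega}\,\mathrm{erfc}(\sqrt{\omega})\right], \quad
#'   \omega = \frac{D t}{\alpha^2 L^2}.}
#' The product `exp(omega) * erfc(sqrt(omega))` is evaluated with the scaled
#' complementary error function ([pracma::erfcx()]) so it neither overflows
#' nor loses precision for large `omega`.
#'
#' Because of the `(1 + alpha)` prefactor the model tends to `1 + alpha`
#' (not 1) as `t` grows; values above 1 are flagged through the
#' `"exceeds_unity"` attribute (and a warning when `warn = TRUE`) but are
#' deliberately not truncated.
#'
#' @inheritParams fractional_release_series
#' @param warn Emit a warning when any returned ratio exceeds 1.
#' @return Numeric vector of fractional release values with attributes
#'   `"omega"` and `"exceeds_unity"`.
#' @export
fractional_release_erfc <- function(t, D, geometry, alpha, warn = TRUE) {
  .check_positive(D = D, alpha = alpha)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0 (seconds)", call. = FALSE)
  L <- .resolve_L(geometry)
  omega <- D * t / (alpha^2 * L^2)
  out <- (1 + alpha) * (1 - .erfcx(sqrt(omega)))
  over <- out > 1
  if (warn && any(over))
    warning(sprintf(
      "%d of %d erfc-model ratios exceed 1 (asymptote is 1 + alpha = %g); ",
      sum(over), length(over), 1 + alpha),
      "values are flagged, not truncated", call. = FALSE)
  attr(out, "omega") <- omega
  attr(out, "exceeds_unity") <- over
  out
}

#' Choose between the series and erfc release models
#'
#' The eigenfunction series is the reference model on its validated range
#' `0.01 <= alpha <= 1000`; below `alpha = 0.01` truncation becomes
#' impractical and the erfc model is used instead. Alphas above 1000 still
#' use the series (it only converges faster there) with a warning that they
#' sit outside the conventionally validated range.
#'
#' @param alpha Dimensionless volume ratio (> 0).
#' @return `"series"` or `"erfc"`.
#' @examples
#' select_model(0.0147)   # "series"
#' select_model(7.34e-4)  # "erfc"
#' @export
select_model <- function(alpha) {
  .check_positive(alpha = alpha)
  if (alpha < 0.01) return("erfc")
  if (alpha > 1000)
    warning(sprintf(
      "alpha = %g is above the validated range 0.01 <= alpha <= 1000; ",
      alpha), "using the series model", call. = FALSE)
  "series"
}

#' Fractional release with automatic model choice
#'
#' Convenience dispatcher: evaluates [fractional_release_series()] or
#' [fractional_release_erfc()] according to [select_model()] (or an explicit
#' `model` override).
#'
#' @inheritParams fractional_release_series
#' @inheritParams fractional_release_erfc
#' @param model `"auto"` (default), `"series"` or `"erfc"`.
#' @return Numeric vector with attribute `"model"`.
#' @export
fractional_release <- function(t, D, geometry, alpha,
                               model = c("auto", "series", "erfc"),
                               roots = NULL, n_roots = 12L, clamp = TRUE,
                               warn = TRUE) {
  model <- match.arg(model)
  if (model == "auto") model <- select_model(alpha)
  out <- switch(model,
    series = fractional_release_series(t, D, geometry, alpha, roots = roots,
                                       n_roots = n_roots, clamp = clamp),
    erfc = fractional_release_erfc(t, D, geometry, alpha, warn = warn))
  attr(out, "model") <- model
  out
}
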