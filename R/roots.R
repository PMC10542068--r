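#' Eigenvalue roots of tan(q) = -alpha * q
#'
#' The limited-volume plane-sheet solution is an eigenfunction expansion
#' whose decay rates are set by the strictly positive roots `q_1 < q_2 < ...`
#' of the transcendental condition `tan(q) = -alpha * q`. The k-th root lies
#' strictly inside `((k - 1/2) * pi, k * pi)`: on that interval
#' `f(q) = tan(q) + alpha * q` rises monotonically from `-Inf` (at the
#' tangent pole) to a positive value, so each bracket holds exactly one
#' root. Roots are located with Brent's method ([stats::uniroot()]) on
#' pole-clipped brackets and polished with a Newton step on the pole-free
#' form `sin(q) + alpha * q * cos(q)`.
#'
#' The trivial root `q = 0` is excluded: it carries no weight in the series
#' (the expansion is over non-zero eigenvalues only).
#'
#' @param alpha Dimensionless volume ratio (> 0); see [compute_alpha()].
#' @param n_roots Number of roots (default 12, the order conventionally used
#'   for `0.01 <= alpha <= 1000`; oracle-grade evaluations use far more, see
#'   [series_roots_needed()]).
#' @param tol Relative root tolerance passed to the bracketing refinement.
#' @return An object of class `root_set`: list with `alpha`, `roots`
#'   (increasing numeric vector), `n_roots`.
#' @examples
#' rs <- find_roots(1)
#' rs$roots[1]  # ~2.0288
#' @export
find_roots <- function(alpha, n_roots = 12L, tol = 1e-12) {
  .check_positive(alpha = alpha)
  n_roots <- as.integer(n_roots)
  if (length(n_roots) != 1L || is.na(n_roots) || n_roots < 1L)
    stop("'n_roots' must be a positive integer", call. = FALSE)

  k <- seq_len(n_roots)
  # clip the brackets away from the tangent poles; for large alpha the
  # k-th root approaches its pole like 1/(alpha k pi), so the lower clip
  # must shrink with alpha to keep the root inside the bracket
  eps <- 1e-9
  lo <- (k - 0.5) * pi + pmin(eps, 0.5 / (alpha * k * pi))
  hi <- k * pi - eps
  f <- function(q) tan(q) + alpha * q
  roots <- vapply(k, function(i) {
    out <- tryCatch(
      stats::uniroot(f, lower = lo[i], upper = hi[i],
                     tol = max(tol * hi[i], 4 * .Machine$double.eps)),
      error = function(e)
        stop(sprintf(
          "bracketing failed for root %d of tan(q) = -%g q on (%.9g, %.9g): %s",
          i, alpha, lo[i], hi[i], conditionMessage(e)), call. = FALSE))
    out$root
  }, numeric(1))

  # one safeguarded Newton polish on g(q) = sin(q) + alpha q cos(q),
  # which is finite through the bracket (no tangent poles)
  g <- sin(roots) + alpha * roots * cos(roots)
  gp <- (1 + alpha) * cos(roots) - alpha * roots * sin(roots)
  step <- ifelse(gp != 0, g / gp, 0)
  polished <- roots - step
  ok <- polished > lo - eps & polished < hi + eps & is.finite(polished)
  roots[ok] <- polished[ok]

  structure(list(alpha = alpha, roots = roots, n_roots = n_roots),
            class = "root_set")
}

#' @export
print.root_set <- function(x, ...) {
  cat(sprintf("Eigenvalue roots of tan(q) = -%g q  (n = %d)\n",
              x$alpha, x$n_roots))
  show_n <- min(x$n_roots, 8L)
  cat("  ", paste(sprintf("%.6f", x$roots[seq_len(show_n)]), collapse = ", "),
      if (x$n_roots > show_n) ", ..." else "", "\n", sep = "")
  cat(sprintf("  max |sin(q) + alpha q cos(q)| / sqrt(1 + (alpha q)^2): %.3g\n",
              max(root_residuals(x))))
  invisible(x)
}

#' Pole-safe residuals of a root set
#'
#' Evaluates `|sin(q) + alpha q cos(q)| / sqrt(1 + (alpha q)^2)`, an
#' algebraic rescaling of `tan(q) + alpha q` that stays well conditioned
#' near the tangent poles (where the raw residual is amplified by
#' `sec^2(q) ~ 1 + (alpha q)^2` and cannot reach small values in double
#' precision for large `alpha`). The scaled residual approximates the
#' distance from `q` to the true root.
#'
#' @param roots A `root_set` from [find_roots()].
#' @return Numeric vector of residual magnitudes.
#' @export
root_residuals <- function(roots) {
  stopifnot(inherits(roots, "root_set"))
  q <- roots$roots
  a <- roots$alpha
  abs(sin(q) + a * q * cos(q)) / sqrt(1 + (a * q)^2)
}

#' Series order needed for a given truncation tolerance
#'
#' The series weights behave as `2 (1 + alpha) / (alpha pi^2 n^2)` for large
#' `n`, so the weight left out by truncating after `N` roots (which is the
#' spurious series value at `t = 0`) is about `2 (1 + alpha) /
#' (alpha pi^2 N)`. Inverting that bound gives the number of roots required
#' to push the truncation deficit below `tol`. For small `alpha` this grows
#' like `1 / alpha` -- the reason the series form is abandoned for the
#' complementary-error-function model when `alpha < 0.01`.
#'
#' @param alpha Dimensionless volume ratio (> 0).
#' @param tol Target truncation deficit (default `1e-3`).
#' @return Integer number of roots (never below 12).
#' @examples
#' series_roots_needed(0.05)   # ~4300
#' series_roots_needed(50)     # 21: large alpha converges fast
#' @export
series_roots_needed <- function(alpha, tol = 1e-3) {
  .check_positive(alpha = alpha, tol = tol)
  max(12L, as.integer(ceiling(2 * (1 + alpha) / (alpha * pi^2 * tol))))
}
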