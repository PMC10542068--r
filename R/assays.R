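#' Swelling ratio of a film after immersion
#'
#' Percent weight gain after 24 h in water:
#' `(W_f - W_i) / W_i * 100`.
#'
#' @param W_i Initial film weight, g (> 0).
#' @param W_f Final film weight, g (>= 0).
#' @return Swelling ratio in percent. Vectorised.
#' @examples
#' swelling_ratio(1, 2)  # 100
#' @export
swelling_ratio <- function(W_i, W_f) {
  if (any(!is.finite(W_i)) || any(W_i <= 0))
    stop("'W_i' must be > 0", call. = FALSE)
  if (any(!is.finite(W_f)) || any(W_f < 0))
    stop("'W_f' must be >= 0", call. = FALSE)
  (W_f - W_i) / W_i * 100
}

#' Percent decrease relative to a reference
#'
#' `(reference - value) / reference * 100`. Values larger than the
#' reference give a negative decrease (i.e. an increase). Full precision is
#' kept; round only for display.
#'
#' @param reference Reference value (> 0).
#' @param value Comparison value (>= 0).
#' @return Percent decrease. Vectorised.
#' @examples
#' percent_decrease(25085, 17282)  # ~31.1
#' @export
percent_decrease <- function(reference, value) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("'reference' must be > 0", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("'value' must be >= 0", call. = FALSE)
  (reference - value) / reference * 100
}

#' Fold change between two positive measurements
#'
#' `treated / control`, e.g. the total-phenolic content of an active film
#' relative to the blank film.
#'
#' @param treated,control Positive values.
#' @return Dimensionless ratio. Vectorised.
#' @examples
#' fold_change(15.47, 2.81)  # ~5.5
#' @export
fold_change <- function(treated, control) {
  if (any(!is.finite(treated)) || any(treated <= 0))
    stop("'treated' must be > 0", call. = FALSE)
  if (any(!is.finite(control)) || any(control <= 0))
    stop("'control' must be > 0", call. = FALSE)
  treated / control
}
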