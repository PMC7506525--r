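#' Frequency band specification
#'
#' A `band_spec` names a frequency band by its lower and upper edge in Hz.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param f_lo Lower band edge in Hz; must satisfy `0 < f_lo < f_hi`.
#' @param f_hi Upper band edge in Hz.
#' @return An object of class `band_spec` (a named list with `name`, `f_lo`,
#'   `f_hi`).
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  f_lo <- as.numeric(f_lo); f_hi <- as.numeric(f_hi)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_lo < f_hi))
    stop("band_spec: need 0 < f_lo < f_hi, got [", f_lo, ", ", f_hi, "]")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical frequency bands
#'
#' The six-band partition used throughout MEG envelope connectomics:
#' delta 2-4, theta 4-8, alpha 8-13, beta 13-30, low gamma 40-60 and
#' high gamma 60-90 Hz.
#'
#' @return A named list of [band_spec] objects.
#' @examples
#' names(canonical_bands())
#' @export
canonical_bands <- function() {
  list(
    delta      = band_spec("delta", 2, 4),
    theta      = band_spec("theta", 4, 8),
    alpha      = band_spec("alpha", 8, 13),
    beta       = band_spec("beta", 13, 30),
    gamma_low  = band_spec("gamma_low", 40, 60),
    gamma_high = band_spec("gamma_high", 60, 90)
  )
}
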