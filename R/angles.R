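# Circular arithmetic helpers. All public interfaces use degrees;
# trigonometry happens in radians at the point of use.

#' Wrap angles to [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval \[0, 360).
#' @export
wrap_angle <- function(x) {
  x %% 360
}

#' Wrap angular differences to (-180, 180]
#'
#' The signed difference convention used throughout: a result of exactly
#' 180 degrees is returned as +180, never -180.
#'
#' @param x Numeric vector of angular differences in degrees.
#' @return Differences wrapped to (-180, 180].
#' @export
wrap_diff <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
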