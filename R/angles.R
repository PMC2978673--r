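#' Wrap an angle into (-pi, pi]
#'
#' Angles are in radians throughout the package, with the allocentric zero
#' along the +X axis (the intended / straight-walk direction) and
#' counterclockwise positive.  Wrapping is idempotent and 2*pi-periodic, and
#' the boundary belongs to +pi: `wrap_angle(pi) == pi`, `wrap_angle(-pi) == pi`.
#'
#' @param a numeric vector of angles in radians; must be finite.
#' @return numeric vector of the same length, each element in (-pi, pi].
#' @examples
#' wrap_angle(3 * pi)        # pi
#' wrap_angle(-3 * pi / 2)   # pi/2
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a))) {
    stop("wrap_angle() requires finite numeric input")
  }
  # map -a into [-pi, pi) and negate, so the half-open side lands on +pi
  -(((-a + pi) %% (2 * pi)) - pi)
}
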