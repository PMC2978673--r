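#' Sense an allocentric heading through a noisy compass
#'
#' Every compass reading carries a fresh, independent Gaussian error
#' `delta`; the reading is wrapped into (-pi, pi].
#'
#' @param true_heading true allocentric heading, radians.
#' @param spec a [noise_spec()] with `input_mode = "compass"`.
#' @param rng an [make_rng()] stream for the delta draws.
#' @return measured heading, radians in (-pi, pi].
#' @export
sense_heading <- function(true_heading, spec, rng) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$input_mode != "compass") {
    stop("sense_heading() requires input_mode = 'compass'")
  }
  wrap_angle(true_heading + rng_normal(rng, length(true_heading),
                                       spec$delta_sd))
}

#' Sense a rotation (heading change) through a noisy channel
#'
#' With `input_mode = "direct_rotation"` the measurement is the true
#' rotation plus a fresh error `delta`.  With
#' `input_mode = "compass_differenced"` the rotation is estimated as the
#' difference of two noisy compass readings, so consecutive errors
#' telescope: the accumulated measurement error over n steps is
#' `delta_n - delta_0`, bounded however long the walk.  The caller threads
#' the previous compass error through `prev_compass_error`; on the first
#' step (`NULL`) a fresh initial reading is drawn.
#'
#' @param true_rotation true rotation since the previous reading, radians.
#' @param spec a [noise_spec()] with `input_mode` `"direct_rotation"` or
#'   `"compass_differenced"`.
#' @param rng an [make_rng()] stream for the delta draws.
#' @param prev_compass_error compass error of the previous reading
#'   (radians), or `NULL` before the first reading; ignored for
#'   `direct_rotation`.
#' @return a list with `measurement` (radians, wrapped) and
#'   `compass_error` (the fresh reading error, to thread into the next
#'   call; `NA` for `direct_rotation`).
#' @export
sense_rotation <- function(true_rotation, spec, rng,
                           prev_compass_error = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!spec$input_mode %in% c("direct_rotation", "compass_differenced")) {
    stop("sense_rotation() requires input_mode 'direct_rotation' or ",
         "'compass_differenced'")
  }
  if (spec$input_mode == "direct_rotation") {
    d <- rng_normal(rng, 1, spec$delta_sd)
    return(list(measurement = wrap_angle(true_rotation + d),
                compass_error = NA_real_))
  }
  if (is.null(prev_compass_error)) {
    prev_compass_error <- rng_normal(rng, 1, spec$delta_sd)
  }
  d <- rng_normal(rng, 1, spec$delta_sd)
  list(measurement = wrap_angle(true_rotation + d - prev_compass_error),
       compass_error = d)
}
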