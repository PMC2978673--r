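#' Noise specification for a path-integration run
#'
#' Two conceptually distinct Gaussian noise sources corrupt path
#' integration.  Input noise `delta` is added to every measured heading or
#' rotation before it reaches the integrator.  Update noise `epsilon` is
#' added to each state parameter that is updated, once per step: angular
#' parameters (the direction component of polar states) receive
#' `eps_angular_sd` radians, linear parameters (Cartesian components, radii,
#' ring moduli) receive `eps_linear_sd` length units.
#'
#' `input_mode` selects how directional input is sensed:
#' * `"compass"` — absolute allocentric heading, error `delta` fresh each
#'   step; only valid for models that take a heading input (AC, AP, ring).
#' * `"direct_rotation"` — the rotation since the previous step, error
#'   `delta` fresh each step; the natural input of egocentric models, and
#'   for heading-input models it turns them into their idiothetic variants
#'   (headings reconstructed by summing measured rotations, so errors
#'   accumulate).
#' * `"compass_differenced"` — rotations estimated as differences of
#'   successive compass readings; consecutive errors telescope, so the
#'   accumulated rotation error after n steps is `delta_n - delta_0`.
#'
#' Defaults are the standard simulation conditions: `pi/36` (5 degrees, or
#' 5-degree-equivalent units for linear parameters) for every noise source.
#'
#' @param delta_sd input noise standard deviation, radians.
#' @param eps_angular_sd update noise on angular state parameters, radians.
#' @param eps_linear_sd update noise on linear state parameters, length units.
#' @param distribution noise distribution; only `"gaussian"` is implemented.
#' @param input_mode one of `"compass"`, `"direct_rotation"`,
#'   `"compass_differenced"`.
#' @return an object of class `noise_spec`.
#' @examples
#' noise_spec()                          # Fig-4-style defaults
#' noise_spec(delta_sd = 0, eps_angular_sd = 0, eps_linear_sd = 0)
#' @export
noise_spec <- function(delta_sd = pi / 36,
                       eps_angular_sd = pi / 36,
                       eps_linear_sd = pi / 36,
                       distribution = "gaussian",
                       input_mode = c("compass", "direct_rotation",
                                      "compass_differenced")) {
  input_mode <- match.arg(input_mode)
  distribution <- match.arg(distribution, "gaussian")
  for (s in c(delta_sd, eps_angular_sd, eps_linear_sd)) {
    stopifnot(is.numeric(s), length(s) == 1, is.finite(s), s >= 0)
  }
  structure(
    list(delta_sd = delta_sd,
         eps_angular_sd = eps_angular_sd,
         eps_linear_sd = eps_linear_sd,
         distribution = distribution,
         input_mode = input_mode),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<noise_spec delta=%.4g eps_ang=%.4g eps_lin=%.4g mode=%s>\n",
    x$delta_sd, x$eps_angular_sd, x$eps_linear_sd, x$input_mode))
  invisible(x)
}

#' Per-step input to a home-vector update
#'
#' Exactly the measurements a representation class needs for one update:
#' heading-input models (AC, AP, ring) require `measured_heading`;
#' rotation-input models (EC, EP) require `measured_rotation`.  The step
#' length `step_length` is the representational step Lambda.
#'
#' @param step_length representational step length (length units, > 0
#'   allowed to be 0 for pure-turn updates).
#' @param measured_heading measured allocentric heading (radians) or `NULL`.
#' @param measured_rotation measured rotation since the previous step
#'   (radians) or `NULL`.
#' @return an object of class `step_input`.
#' @export
step_input <- function(step_length, measured_heading = NULL,
                       measured_rotation = NULL) {
  stopifnot(is.numeric(step_length), length(step_length) == 1,
            is.finite(step_length), step_length >= 0)
  structure(
    list(step_length = step_length,
         measured_heading = measured_heading,
         measured_rotation = measured_rotation),
    class = "step_input"
  )
}
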