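# Deterministic single-step update cores.  The exported update_*()
# wrappers draw their epsilon terms from an rng stream; run_pi() pre-draws
# whole noise sequences and calls the cores directly so that closed-form
# neural records can be checked pathwise against the same realization.

.ac_core <- function(u, v, theta, lambda, eps_u = 0, eps_v = 0) {
  list(u = u + lambda * cos(theta) + eps_u,
       v = v + lambda * sin(theta) + eps_v)
}

.ap_core <- function(r, phi, theta, lambda, eps_r = 0, eps_phi = 0) {
  x <- r * cos(phi) + lambda * cos(theta)
  y <- r * sin(phi) + lambda * sin(theta)
  r_new <- sqrt(x^2 + y^2) + eps_r
  clipped <- r_new < 0
  list(r = max(r_new, 0),
       phi = wrap_angle(atan2(y, x) + eps_phi),
       clipped = clipped)
}

# egocentric Cartesian: rotation of the animal by dtheta counter-rotates
# home in the body frame; a forward step of lambda moves home backward
.ec_core <- function(u, v, rotation, lambda, eps_u = 0, eps_v = 0) {
  cu <- cos(rotation); su <- sin(rotation)
  u_rot <- cu * u + su * v
  v_rot <- -su * u + cu * v
  list(u_prime = u_rot - lambda + eps_u,
       v_prime = v_rot + eps_v)
}

.ep_core <- function(r, phi, rotation, lambda, eps_r = 0, eps_phi = 0) {
  phi <- phi - rotation
  x <- r * cos(phi) - lambda
  y <- r * sin(phi)
  r_new <- sqrt(x^2 + y^2) + eps_r
  clipped <- r_new < 0
  list(r_prime = max(r_new, 0),
       phi_prime = wrap_angle(atan2(y, x) + eps_phi),
       clipped = clipped)
}

.ring_core <- function(moduli, dirs, theta, lambda, eps = 0) {
  moduli + lambda * cos(theta - dirs) + eps
}

#' Single home-vector update for each representation class
#'
#' Applies one discrete-time path-integration update.  Measured inputs
#' (already carrying the input noise `delta`) come in `inp`; the update
#' noise `epsilon` is drawn from `rng` once per updated state parameter:
#'
#' * `update_ac`: `u += Lambda cos(theta~) + eps_u`,
#'   `v += Lambda sin(theta~) + eps_v` (linear `eps`).
#' * `update_ap`: exact polar recomputation of the new vector from
#'   `(r, phi)` and the step `(Lambda, theta~)`, then `r += eps_r` (clipped
#'   at 0, clipping flagged) and `phi += eps_phi`; the angular update
#'   error rotates the entire accumulated representation.
#' * `update_ec`: rotate `(u', v')` by `-rotation~` (the animal turns, so
#'   home counter-rotates in the body frame), then `u' -= Lambda` (a
#'   forward step moves home backward), then add linear `eps`.
#' * `update_ep`: `phi' -= rotation~`, exact polar incorporation of the
#'   backward home shift by `Lambda`, then `r' += eps_r'` (clipped) and
#'   `phi' += eps_phi'`.
#' * `update_ring`: every unit accumulates
#'   `Lambda cos(theta~ - preferred_dir) + eps_i` (iid linear `eps`).
#'
#' @param state a state object of the matching class, see [hv_states].
#' @param inp a [step_input()]; heading-input classes (AC, AP, ring)
#'   require `measured_heading`, rotation-input classes (EC, EP) require
#'   `measured_rotation`.
#' @param spec a [noise_spec()] supplying the epsilon standard deviations.
#' @param rng an [make_rng()] stream for the epsilon draws.
#' @return the updated state object.  For polar states the attribute
#'   `"clipped"` reports whether the radius was clipped at zero.
#' @name hv_updates
NULL

.need <- function(inp, field) {
  if (is.null(inp[[field]])) {
    stop("step_input is missing the required field '", field, "'")
  }
  inp[[field]]
}

#' @rdname hv_updates
#' @export
update_ac <- function(state, inp, spec, rng) {
  stopifnot(inherits(state, "ac_state"), inherits(inp, "step_input"))
  theta <- .need(inp, "measured_heading")
  eps <- rng_normal(rng, 2, spec$eps_linear_sd)
  s <- .ac_core(state$u, state$v, theta, inp$step_length, eps[1], eps[2])
  ac_state(s$u, s$v)
}

#' @rdname hv_updates
#' @export
update_ap <- function(state, inp, spec, rng) {
  stopifnot(inherits(state, "ap_state"), inherits(inp, "step_input"))
  theta <- .need(inp, "measured_heading")
  eps_r <- rng_normal(rng, 1, spec$eps_linear_sd)
  eps_phi <- rng_normal(rng, 1, spec$eps_angular_sd)
  s <- .ap_core(state$r, state$phi, theta, inp$step_length, eps_r, eps_phi)
  out <- ap_state(s$r, s$phi)
  attr(out, "clipped") <- s$clipped
  out
}

#' @rdname hv_updates
#' @export
update_ec <- function(state, inp, spec, rng) {
  stopifnot(inherits(state, "ec_state"), inherits(inp, "step_input"))
  rot <- .need(inp, "measured_rotation")
  eps <- rng_normal(rng, 2, spec$eps_linear_sd)
  s <- .ec_core(state$u_prime, state$v_prime, rot, inp$step_length,
                eps[1], eps[2])
  ec_state(s$u_prime, s$v_prime)
}

#' @rdname hv_updates
#' @export
update_ep <- function(state, inp, spec, rng) {
  stopifnot(inherits(state, "ep_state"), inherits(inp, "step_input"))
  rot <- .need(inp, "measured_rotation")
  eps_r <- rng_normal(rng, 1, spec$eps_linear_sd)
  eps_phi <- rng_normal(rng, 1, spec$eps_angular_sd)
  s <- .ep_core(state$r_prime, state$phi_prime, rot, inp$step_length,
                eps_r, eps_phi)
  out <- ep_state(s$r_prime, s$phi_prime)
  attr(out, "clipped") <- s$clipped
  out
}

#' @rdname hv_updates
#' @export
update_ring <- function(state, inp, spec, rng) {
  stopifnot(inherits(state, "ring_state"), inherits(inp, "step_input"))
  theta <- .need(inp, "measured_heading")
  eps <- rng_normal(rng, state$n_units, spec$eps_linear_sd)
  ring_state(state$n_units,
             moduli = .ring_core(state$moduli, state$preferred_dirs,
                                 theta, inp$step_length, eps))
}
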