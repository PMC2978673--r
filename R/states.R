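#' Home-vector state representations
#'
#' One constructor per representation class.  Allocentric states store the
#' animal's position relative to home; egocentric states store home's
#' position in the animal's body frame (+U' rostral/forward, +V' left).
#' [decode_hv()] reconciles the conventions: it always returns the
#' allocentric estimate of the animal's position relative to home.
#'
#' * `ac_state(u, v)` — allocentric Cartesian (an allocentric static
#'   vectorial representation, ASVR).
#' * `ap_state(r, phi)` — allocentric polar: distance and allocentric
#'   direction of the animal from home (allocentric dynamic vectorial,
#'   ADVR).
#' * `ec_state(u_prime, v_prime)` — egocentric Cartesian: home in the body
#'   frame; negative U'/V' mean backward/rightward (egocentric static
#'   vectorial, ESVR).
#' * `ep_state(r_prime, phi_prime)` — egocentric polar: distance and
#'   bearing of home from the animal, bearing measured from +U'
#'   (egocentric dynamic vectorial, EDVR).
#' * `ring_state(n_units)` — N static, evenly spaced preferred directions
#'   with dynamic signed moduli (a ring-like ASVR with variable-length
#'   static vectors).
#'
#' @param u,v allocentric Cartesian components, length units.
#' @param r,r_prime non-negative distances, length units.
#' @param phi,phi_prime angles, radians (wrapped on construction).
#' @param u_prime,v_prime egocentric Cartesian components, length units.
#' @param n_units number of ring units, >= 2.
#' @param moduli optional initial moduli (defaults to zeros).
#' @return a state object of class `ac_state`, `ap_state`, `ec_state`,
#'   `ep_state` or `ring_state` (all also `hv_state`).
#' @name hv_states
NULL

.hv_state <- function(fields, class) {
  structure(fields, class = c(class, "hv_state"))
}

#' @rdname hv_states
#' @export
ac_state <- function(u = 0, v = 0) {
  stopifnot(is.finite(u), is.finite(v))
  .hv_state(list(u = u, v = v), "ac_state")
}

#' @rdname hv_states
#' @export
ap_state <- function(r = 0, phi = 0) {
  stopifnot(is.finite(r), r >= 0, is.finite(phi))
  .hv_state(list(r = r, phi = wrap_angle(phi)), "ap_state")
}

#' @rdname hv_states
#' @export
ec_state <- function(u_prime = 0, v_prime = 0) {
  stopifnot(is.finite(u_prime), is.finite(v_prime))
  .hv_state(list(u_prime = u_prime, v_prime = v_prime), "ec_state")
}

#' @rdname hv_states
#' @export
ep_state <- function(r_prime = 0, phi_prime = 0) {
  stopifnot(is.finite(r_prime), r_prime >= 0, is.finite(phi_prime))
  .hv_state(list(r_prime = r_prime, phi_prime = wrap_angle(phi_prime)),
            "ep_state")
}

#' @rdname hv_states
#' @export
ring_state <- function(n_units = 16, moduli = NULL) {
  if (!is.numeric(n_units) || n_units < 2) {
    stop("ring_state requires n_units >= 2")
  }
  n_units <- as.integer(n_units)
  dirs <- if (n_units == 2) c(0, pi / 2) else
    2 * pi * (seq_len(n_units) - 1) / n_units
  if (is.null(moduli)) moduli <- numeric(n_units)
  stopifnot(length(moduli) == n_units, all(is.finite(moduli)))
  .hv_state(list(n_units = n_units, preferred_dirs = wrap_angle(dirs),
                 moduli = moduli), "ring_state")
}

#' @export
print.hv_state <- function(x, ...) {
  nm <- class(x)[1]
  vals <- unlist(x[vapply(x, is.numeric, TRUE)])
  cat(sprintf("<%s %s>\n", nm,
              paste(sprintf("%s=%.4g", names(vals), vals)[seq_len(min(6, length(vals)))],
                    collapse = " ")))
  invisible(x)
}

#' Decode a state into an allocentric home-vector estimate
#'
#' Returns the represented allocentric position of the animal relative to
#' home, `c(x_hat, y_hat)`.  Egocentric states are mapped through the
#' animal's true current heading (the metric, not the model, sees ground
#' truth) and negated, since they store home relative to the animal.  The
#' ring state is decoded by least-squares projection of the moduli onto
#' the two first-harmonic components of the preferred directions, the
#' exact inverse of the noise-free encoding.
#'
#' @param state an `hv_state`.
#' @param true_heading the animal's true allocentric heading, radians
#'   (used only by egocentric states).
#' @return numeric length-2 vector `c(x_hat, y_hat)`.
#' @examples
#' decode_hv(ac_state(3, 4))                 # (3, 4)
#' decode_hv(ec_state(-1, 0), true_heading = 0)  # (1, 0)
#' @export
decode_hv <- function(state, true_heading = 0) {
  UseMethod("decode_hv")
}

#' @export
decode_hv.ac_state <- function(state, true_heading = 0) {
  c(state$u, state$v)
}

#' @export
decode_hv.ap_state <- function(state, true_heading = 0) {
  state$r * c(cos(state$phi), sin(state$phi))
}

# body frame -> allocentric rotation: v_allo = R(heading) %*% v_ego
.ego_to_allo <- function(v, heading) {
  c(cos(heading) * v[1] - sin(heading) * v[2],
    sin(heading) * v[1] + cos(heading) * v[2])
}

#' @export
decode_hv.ec_state <- function(state, true_heading = 0) {
  -.ego_to_allo(c(state$u_prime, state$v_prime), true_heading)
}

#' @export
decode_hv.ep_state <- function(state, true_heading = 0) {
  home_ego <- state$r_prime * c(cos(state$phi_prime), sin(state$phi_prime))
  -.ego_to_allo(home_ego, true_heading)
}

#' @export
decode_hv.ring_state <- function(state, true_heading = 0) {
  C <- cbind(cos(state$preferred_dirs), sin(state$preferred_dirs))
  as.numeric(qr.coef(qr(C), state$moduli))
}
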