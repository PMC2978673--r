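#' Run path integration along a trajectory
#'
#' Drives one representation class step by step along a ground-truth
#' trajectory, corrupting directional inputs with `delta` and every state
#' update with `epsilon`, and records the decoded home-vector estimate and
#' its positional error (Euclidean distance between the decoded position
#' and the true position) after every step.
#'
#' Input sensing follows the class's natural channel.  Heading-input
#' classes (`"ac"`, `"ap"`, `"ring"`) read a compass each step
#' (`input_mode = "compass"`), or integrate noisy rotation measurements
#' into a heading estimate (`input_mode = "direct_rotation"`, the
#' idiothetic variant; the turn into step k is sensed with a fresh error,
#' so errors accumulate as `delta_1 + ... + delta_k`).  Rotation-input
#' classes (`"ec"`, `"ep"`) sense their rotation when a step completes:
#' the reading taken at the end of step k (fresh error `delta_k`, or a
#' compass difference when `input_mode = "compass_differenced"`) rotates
#' the whole record after step k's translation has been incorporated,
#' including a final reading after the last step.  Consequently the
#' closed-form neural record of step m accumulates exactly the input
#' errors `delta_m .. delta_n` (see [nr_record()]), and decoding at step k
#' uses the heading the animal faces after that reading (the heading of
#' step k+1; of step n after the final step).
#'
#' @param traj a [real_trajectory()].
#' @param class one of `"ac"`, `"ap"`, `"ec"`, `"ep"`, `"ring"`.
#' @param spec a [noise_spec()]; its `input_mode` must be compatible with
#'   the class (`"compass"` is only for heading-input classes,
#'   `"compass_differenced"` only for rotation-input classes).
#' @param rng an integer seed (streams `"delta"` and `"eps"` are derived
#'   from it, so two classes run with the same seed receive identical
#'   input-noise draws) or a list `list(delta = , eps = )` of
#'   [make_rng()] streams.
#' @param n_units ring size when `class = "ring"`.
#' @param noise optional pre-drawn noise realization, a list with elements
#'   `delta` (length n, or n+1 for `compass_differenced`, ordered
#'   `delta_0..delta_n`), `eps_angular` (length n) and `eps_linear`
#'   (n x 2 matrix, or n x n_units for the ring).  Used by matched-noise
#'   oracles; when supplied no random draws are made.
#' @return an object of class `hv_trace`: a data.frame with rows for steps
#'   `0..n`, class-specific state columns, `x_hat`, `y_hat` and
#'   `pos_error`, plus attributes `model_class`, `spec`, `n_clipped` (radius
#'   clipping events in polar states) and `noise` (the realization used).
#' @examples
#' tr <- turning_walk(20, 1, 0.1, make_rng(1, "path"))
#' run_pi(tr, "ac", noise_spec(), rng = 1)
#' @export
run_pi <- function(traj, class = c("ac", "ap", "ec", "ep", "ring"),
                   spec = noise_spec(), rng = 1, n_units = 16,
                   noise = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(traj, "real_trajectory"), inherits(spec, "noise_spec"))
  n <- traj$n_steps
  heading_input <- class %in% c("ac", "ap", "ring")
  if (heading_input && spec$input_mode == "compass_differenced") {
    stop("input_mode 'compass_differenced' applies to rotation-input ",
         "classes (ec, ep)")
  }
  if (!heading_input && spec$input_mode == "compass") {
    stop("input_mode 'compass' applies to heading-input classes ",
         "(ac, ap, ring); egocentric classes take rotations")
  }

  if (is.list(rng) && !inherits(rng, "rng_stream")) {
    delta_rng <- rng$delta; eps_rng <- rng$eps
  } else {
    seed <- rng
    delta_rng <- make_rng(seed, "delta")
    eps_rng <- make_rng(seed, "eps")
  }

  noise <- .draw_noise(class, spec, n, n_units, delta_rng, eps_rng, noise)
  trace <- .simulate_trace(class, traj, spec, noise, n_units)
  attr(trace, "spec") <- spec
  attr(trace, "noise") <- noise
  trace
}

.draw_noise <- function(class, spec, n, n_units, delta_rng, eps_rng,
                        noise) {
  n_delta <- if (spec$input_mode == "compass_differenced") n + 1 else n
  n_lin <- switch(class, ring = n_units, 2)
  if (is.null(noise)) {
    noise <- list(
      delta = rng_normal(delta_rng, n_delta, spec$delta_sd),
      eps_linear = matrix(rng_normal(eps_rng, n * n_lin,
                                     spec$eps_linear_sd), n, n_lin),
      eps_angular = rng_normal(eps_rng, n, spec$eps_angular_sd)
    )
  }
  stopifnot(length(noise$delta) == n_delta,
            length(noise$eps_angular) == n)
  noise$eps_linear <- matrix(noise$eps_linear, n, n_lin)
  noise
}

.simulate_trace <- function(class, traj, spec, noise, n_units) {
  n <- traj$n_steps
  h <- traj$headings
  lam <- traj$step_lengths
  delta <- noise$delta
  eps_l <- noise$eps_linear
  eps_a <- noise$eps_angular
  n_clipped <- 0L

  if (class %in% c("ac", "ap", "ring")) {
    theta_meas <- if (n == 0) numeric(0)
      else if (spec$input_mode == "compass") h + delta
      else cumsum(traj$turns + delta)  # idiothetic heading integration
  } else {
    # end-of-step rotation readings: turn out of step k (into step k+1;
    # zero after the final step), sensed with error delta_k
    turn_out <- if (n == 0) numeric(0) else c(traj$turns[-1], 0)
    h_faced <- if (n == 0) numeric(0) else c(h[-1], h[n])
    rot_meas <- if (n == 0) {
      numeric(0)
    } else if (spec$input_mode == "direct_rotation") {
      turn_out + delta
    } else {
      # compass reading after the end-of-step-k turn is h_faced_k + delta_k;
      # the initial reading (error delta_0 = delta[1]) is taken at the walk
      # start, facing the first step's heading
      readings <- c(h[1] + delta[1], h_faced + delta[-1])
      diff(readings)
    }
  }

  state_cols <- switch(class,
    ac = c("u", "v"), ap = c("r", "phi"),
    ec = c("u_prime", "v_prime"), ep = c("r_prime", "phi_prime"),
    ring = sprintf("m%02d", seq_len(n_units)))
  S <- matrix(0, n + 1, length(state_cols),
              dimnames = list(NULL, state_cols))
  xy <- matrix(0, n + 1, 2)
  perr <- numeric(n + 1)
  dirs <- if (class == "ring") ring_state(n_units)$preferred_dirs

  st <- switch(class, ac = ac_state(), ap = ap_state(), ec = ec_state(),
               ep = ep_state(), ring = ring_state(n_units))
  for (k in seq_len(n)) {
    if (class == "ac") {
      s <- .ac_core(st$u, st$v, theta_meas[k], lam[k],
                    eps_l[k, 1], eps_l[k, 2])
      st <- ac_state(s$u, s$v)
      dec <- decode_hv(st)
    } else if (class == "ap") {
      s <- .ap_core(st$r, st$phi, theta_meas[k], lam[k],
                    eps_l[k, 1], eps_a[k])
      if (s$clipped) n_clipped <- n_clipped + 1L
      st <- ap_state(s$r, s$phi)
      dec <- decode_hv(st)
    } else if (class == "ring") {
      st <- ring_state(n_units,
                       moduli = .ring_core(st$moduli, dirs, theta_meas[k],
                                           lam[k], eps_l[k, ]))
      dec <- decode_hv(st)
    } else if (class == "ec") {
      # step k lands (translate + update noise), then the end-of-step
      # rotation reading turns the whole record
      s <- .ec_core(st$u_prime, st$v_prime, 0, lam[k],
                    eps_l[k, 1], eps_l[k, 2])
      s <- .ec_core(s$u_prime, s$v_prime, rot_meas[k], 0)
      st <- ec_state(s$u_prime, s$v_prime)
      dec <- decode_hv(st, true_heading = h_faced[k])
    } else { # ep
      s <- .ep_core(st$r_prime, st$phi_prime, 0, lam[k],
                    eps_l[k, 1], eps_a[k])
      if (s$clipped) n_clipped <- n_clipped + 1L
      s <- .ep_core(s$r_prime, s$phi_prime, rot_meas[k], 0)
      st <- ep_state(s$r_prime, s$phi_prime)
      dec <- decode_hv(st, true_heading = h_faced[k])
    }
    S[k + 1, ] <- unlist(st[switch(class,
      ac = c("u", "v"), ap = c("r", "phi"),
      ec = c("u_prime", "v_prime"), ep = c("r_prime", "phi_prime"),
      ring = "moduli")], use.names = FALSE)
    xy[k + 1, ] <- dec
    perr[k + 1] <- sqrt(sum((dec - traj$positions[k + 1, ])^2))
  }

  trace <- data.frame(step = 0:n, S, xy[, 1], xy[, 2], perr)
  names(trace) <- c("step", state_cols, "x_hat", "y_hat", "pos_error")
  structure(trace,
            class = c("hv_trace", "data.frame"),
            model_class = class, n_clipped = n_clipped)
}

#' @export
print.hv_trace <- function(x, ...) {
  n <- nrow(x) - 1
  cat(sprintf("<hv_trace class=%s n_steps=%d final_pos_error=%.4g>\n",
              attr(x, "model_class"), n, x$pos_error[n + 1]))
  invisible(x)
}

#' Write a home-vector trace as CSV
#'
#' Layout `step,<state columns>,x_hat,y_hat,pos_error`; the state columns
#' are class-dependent (`u,v` for AC; `r,phi` for AP; `u_prime,v_prime`
#' for EC; `r_prime,phi_prime` for EP; `m01..mNN` for the ring).
#'
#' @param trace an `hv_trace` from [run_pi()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hv_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
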