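#' Directed-walk generators in physical space
#'
#' A directed walk is a sequence of discrete steps all intended along the
#' +X axis.  In an allothetic directed walk (ADW) the agent re-reads an
#' external compass each step, so per-step heading errors are fresh and do
#' not accumulate.  In an idiothetic directed walk (IDW) heading is kept by
#' integrating rotations, so per-step turn errors accumulate: the heading
#' of step k is the sum of all turn errors up to and including step k.
#'
#' Convention: the first step already carries a turn/heading error (the
#' agent errs before its first step lands).  This matters for closed-form
#' moments, e.g. the IDW mean-displacement limit is `L * c / (1 - c)` with
#' `c = E[cos delta]`.
#'
#' @param n number of steps (>= 0 for `straight_walk`, >= 1 otherwise).
#' @param L step length, > 0.
#' @param delta_sd per-step angular error standard deviation, radians.
#' @param turn_sd per-step turn standard deviation, radians (the turning
#'   walk is structurally an IDW; the parameter is named for its role as
#'   ground-truth locomotion).
#' @param rng an [make_rng()] stream or an integer seed.
#' @return a [real_trajectory()].
#' @examples
#' adw(5, 1, 0, make_rng(1, "demo"))$positions  # noise-free: straight line
#' @name directed_walks
NULL

#' @rdname directed_walks
#' @export
straight_walk <- function(n, L = 1) {
  stopifnot(n >= 0, L > 0)
  real_trajectory(headings = rep(0, n), step_lengths = L)
}

#' @rdname directed_walks
#' @export
adw <- function(n, L = 1, delta_sd = pi / 36, rng = 1) {
  stopifnot(n >= 1, L > 0)
  rng <- .as_rng(rng, "adw")
  real_trajectory(headings = rng_normal(rng, n, delta_sd), step_lengths = L)
}

#' @rdname directed_walks
#' @export
idw <- function(n, L = 1, delta_sd = pi / 36, rng = 1) {
  stopifnot(n >= 1, L > 0)
  rng <- .as_rng(rng, "idw")
  real_trajectory(headings = cumsum(rng_normal(rng, n, delta_sd)),
                  step_lengths = L)
}

#' @rdname directed_walks
#' @export
turning_walk <- function(n, L = 1, turn_sd = 0.1, rng = 1) {
  stopifnot(n >= 1, L > 0)
  rng <- .as_rng(rng, "path-turns")
  real_trajectory(headings = cumsum(rng_normal(rng, n, turn_sd)),
                  step_lengths = L)
}

#' General biased elementary step model
#'
#' Describes one unit of locomotion: a turn with mean `mean_turn` (bias)
#' and sd `turn_sd`, and a step length with mean `mean_length` and sd
#' `length_sd`, with a Gaussian-copula correlation between turn and length
#' deviations.  Covers any locomotory pattern at the simulation level; no
#' closed-form moments are provided for it.
#'
#' @param mean_turn turn bias, radians.
#' @param turn_sd turn standard deviation, radians, >= 0.
#' @param mean_length mean step length, > 0.
#' @param length_sd step length standard deviation, >= 0.
#' @param turn_length_correlation correlation in `[-1, 1]`.
#' @return an object of class `step_model`.
#' @export
step_model <- function(mean_turn = 0, turn_sd = 0, mean_length = 1,
                       length_sd = 0, turn_length_correlation = 0) {
  stopifnot(turn_sd >= 0, length_sd >= 0, mean_length > 0)
  if (!is.finite(turn_length_correlation) ||
      abs(turn_length_correlation) > 1) {
    stop("turn_length_correlation must lie in [-1, 1]")
  }
  structure(
    list(mean_turn = mean_turn, turn_sd = turn_sd,
         mean_length = mean_length, length_sd = length_sd,
         turn_length_correlation = turn_length_correlation),
    class = "step_model"
  )
}

#' Walk built from general biased elementary steps
#'
#' Turn and length deviations are drawn jointly (Gaussian copula for the
#' stated correlation); lengths are truncated at zero by redrawing the
#' length deviation.  `mode = "idw"` accumulates turns into headings
#' (heading k = sum of the first k turns); `mode = "adw"` treats each
#' drawn turn deviation as a fresh heading error about the intended
#' heading `k * mean_turn`.
#'
#' @param n number of steps, >= 1.
#' @param model a [step_model()].
#' @param rng an [make_rng()] stream or an integer seed.
#' @param mode `"idw"` (turn errors accumulate) or `"adw"` (fresh errors).
#' @return a [real_trajectory()].
#' @export
biased_step_walk <- function(n, model, rng = 1, mode = c("idw", "adw")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, inherits(model, "step_model"))
  rng <- .as_rng(rng, "biased-steps")
  z1 <- rng_normal(rng, n)
  z2 <- rng_normal(rng, n)
  rho <- model$turn_length_correlation
  turn_dev <- model$turn_sd * z1
  len_dev <- model$length_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  lengths <- model$mean_length + len_dev
  # truncate at zero: redraw the length deviation only (keeps turns matched)
  bad <- which(lengths <= 0)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    znew <- rng_normal(rng, length(bad))
    lengths[bad] <- model$mean_length +
      model$length_sd * (rho * z1[bad] + sqrt(1 - rho^2) * znew)
    bad <- which(lengths <= 0)
    tries <- tries + 1
  }
  if (length(bad) > 0) stop("could not draw positive step lengths")
  headings <- if (mode == "idw") {
    cumsum(model$mean_turn + turn_dev)
  } else {
    seq_len(n) * model$mean_turn + turn_dev
  }
  real_trajectory(headings = headings, step_lengths = lengths)
}
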