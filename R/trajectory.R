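#' Physical-space trajectory of a walking agent
#'
#' A `real_trajectory` stores the ground-truth walk that a path integrator
#' must track: per-step headings, turn angles (heading differences), step
#' lengths, and the positions they imply.  Step indexing is 1-based;
#' position row `k + 1` is the location after step `k`, row 1 is home (the
#' origin).  The heading "before" step 1 defines the frame of the first
#' turn and is 0 by convention (the intended / +X axis).
#'
#' @param headings numeric vector of per-step allocentric headings, radians.
#' @param step_lengths numeric vector of per-step lengths (recycled from a
#'   scalar), all > 0 unless the walk is empty.
#' @return an object of class `real_trajectory` with fields `n_steps`,
#'   `positions` ((n+1) x 2 matrix), `headings`, `turns`, `step_lengths`.
#' @examples
#' tr <- real_trajectory(headings = c(0, pi / 2), step_lengths = 1)
#' tr$positions  # home, (1,0), (1,1)
#' @export
real_trajectory <- function(headings, step_lengths = 1) {
  n <- length(headings)
  if (n > 0) {
    stopifnot(is.numeric(headings), all(is.finite(headings)))
  }
  step_lengths <- rep_len(as.numeric(step_lengths), n)
  if (n > 0) stopifnot(all(is.finite(step_lengths)), all(step_lengths > 0))
  headings <- if (n > 0) wrap_angle(headings) else numeric(0)
  turns <- if (n > 0) wrap_angle(diff(c(0, headings))) else numeric(0)
  positions <- cbind(
    x = c(0, cumsum(step_lengths * cos(headings))),
    y = c(0, cumsum(step_lengths * sin(headings)))
  )
  structure(
    list(n_steps = n, positions = positions, headings = headings,
         turns = turns, step_lengths = step_lengths),
    class = "real_trajectory"
  )
}

#' @export
print.real_trajectory <- function(x, ...) {
  ep <- x$positions[nrow(x$positions), ]
  cat(sprintf("<real_trajectory n_steps=%d endpoint=(%.3f, %.3f)>\n",
              x$n_steps, ep[1], ep[2]))
  invisible(x)
}

#' Convert a trajectory to the canonical data frame layout
#'
#' Columns `step, x, y, heading, turn, step_length`; the step-0 row is the
#' home/origin carrying the frame heading of the first step (0) and zero
#' turn and length.
#'
#' @param x a [real_trajectory()].
#' @param ... unused.
#' @return a data.frame with `n_steps + 1` rows.
#' @export
as.data.frame.real_trajectory <- function(x, ...) {
  data.frame(
    step = 0:x$n_steps,
    x = x$positions[, 1],
    y = x$positions[, 2],
    heading = c(0, x$headings),
    turn = c(0, x$turns),
    step_length = c(0, x$step_lengths)
  )
}

#' Write / read a trajectory as CSV
#'
#' The CSV dialect is the data-frame layout of
#' [as.data.frame.real_trajectory()]: header
#' `step,x,y,heading,turn,step_length`, angles in radians, 1-based step
#' indices with a step-0 origin row.
#'
#' @param traj a [real_trajectory()].
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a [real_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("step", "x", "y", "heading", "turn", "step_length")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  }
  df <- df[order(df$step), ]
  if (df$step[1] != 0) stop("trajectory CSV must contain the step-0 home row")
  steps <- df[-1, , drop = FALSE]
  tr <- real_trajectory(headings = steps$heading,
                        step_lengths = steps$step_length)
  # positions are implied by headings/lengths; check the file is consistent
  if (nrow(steps) > 0) {
    err <- max(abs(tr$positions[-1, 1] - steps$x),
               abs(tr$positions[-1, 2] - steps$y))
    if (err > 1e-6) {
      stop("trajectory CSV positions inconsistent with headings/lengths ",
           sprintf("(max discrepancy %.3g)", err))
    }
  }
  tr
}
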