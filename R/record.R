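#' Error sequences driving a closed-form neural record
#'
#' Holds one realization of the per-step noise of a journey: input errors
#' `delta_1..delta_n`, angular update errors `eps_1..eps_n`, and the
#' representational step lengths `Lambda_1..Lambda_n`.  Optional per-step
#' linear update components `eps_u`, `eps_v` are used only by the
#' allocentric static class (they add to its record vectors; linear update
#' noise otherwise folds into `Lambda`).
#'
#' @param delta numeric vector of input errors, radians.
#' @param eps_angular numeric vector of angular update errors, radians.
#' @param step_lengths numeric vector of step lengths (recycled from a
#'   scalar).
#' @param eps_u,eps_v optional per-step linear update errors (length n or
#'   `NULL`).
#' @return an object of class `error_sequences`.
#' @export
error_sequences <- function(delta, eps_angular = 0 * delta,
                            step_lengths = 1, eps_u = NULL, eps_v = NULL) {
  n <- length(delta)
  eps_angular <- rep_len(as.numeric(eps_angular), n)
  step_lengths <- rep_len(as.numeric(step_lengths), n)
  if (!is.null(eps_u)) eps_u <- rep_len(as.numeric(eps_u), n)
  if (!is.null(eps_v)) eps_v <- rep_len(as.numeric(eps_v), n)
  stopifnot(all(is.finite(delta)), all(is.finite(eps_angular)),
            all(is.finite(step_lengths)))
  structure(list(delta = as.numeric(delta), eps_angular = eps_angular,
                 step_lengths = step_lengths, eps_u = eps_u, eps_v = eps_v,
                 n = n),
            class = "error_sequences")
}

.record_classes <- c("esvr", "advr", "edvr", "asvr", "asvr_idiothetic")

# record angle alpha(m, n) for one class: the angular deviation of the
# neural record of step m from the true step direction, after n steps
.record_angle <- function(class, seqs, m, n) {
  d <- seqs$delta; e <- seqs$eps_angular
  switch(class,
    esvr = -sum(d[m:n]),
    advr = sum(e[m:n]),
    edvr = sum(e[m:n] - d[m:n]),
    asvr = d[m],
    asvr_idiothetic = sum(d[1:m]),
    stop("unknown record class '", class, "'"))
}

#' Closed-form neural record of one step
#'
#' The neural record decomposes the final path-integration state after n
#' steps of a straight physical walk into per-step vectors, showing how
#' each original step appears once all errors up to step n have acted.
#' The record of step m is `Lambda_m * (cos a, sin a)` with record angle
#' `a` depending on the representation class:
#'
#' * `"esvr"` (egocentric static, e.g. EC): `a = -(delta_m + .. + delta_n)`
#'   — every later input error has rotated the whole record, so the class
#'   behaves as an idiothetic directed walk in representational space,
#'   accumulating in reverse temporal order.
#' * `"advr"` (allocentric dynamic, e.g. AP): `a = eps_m + .. + eps_n`.
#' * `"edvr"` (egocentric dynamic, e.g. EP): `a = sum(eps_k - delta_k)`,
#'   k = m..n.
#' * `"asvr"` (allocentric static, e.g. AC): `a = delta_m` only — no
#'   coupling across steps, the allothetic-directed-walk signature.  When
#'   the sequences carry linear components `eps_u`, `eps_v`, they add to
#'   the record vector.
#' * `"asvr_idiothetic"`: an allocentric static representation fed only
#'   rotation measurements: `a = delta_1 + .. + delta_m` (forward
#'   accumulation).
#'
#' @param class one of `"esvr"`, `"advr"`, `"edvr"`, `"asvr"`,
#'   `"asvr_idiothetic"`.
#' @param seqs an [error_sequences()].
#' @param m step index, `1 <= m <= n`.
#' @param n total number of steps, `n <= length(seqs$delta)`.
#' @return a list of class `record_step` with fields `m`, `angle`,
#'   `vector` (length-2 numeric).
#' @export
nr_record <- function(class, seqs, m, n = seqs$n) {
  class <- match.arg(class, .record_classes)
  stopifnot(inherits(seqs, "error_sequences"))
  if (!(m >= 1 && m <= n && n <= seqs$n)) {
    stop("record indices must satisfy 1 <= m <= n <= length(sequences)")
  }
  a <- .record_angle(class, seqs, m, n)
  vec <- seqs$step_lengths[m] * c(cos(a), sin(a))
  if (class == "asvr" && !is.null(seqs$eps_u)) {
    vec <- vec + c(seqs$eps_u[m], seqs$eps_v[m])
  }
  structure(list(m = m, angle = a, vector = vec), class = "record_step")
}

#' All neural records of a journey
#'
#' @inheritParams nr_record
#' @return a data.frame with columns `m`, `angle`, `u`, `v` (one row per
#'   step, the CSV export layout).
#' @export
nr_records <- function(class, seqs, n = seqs$n) {
  rows <- lapply(seq_len(n), function(m) {
    r <- nr_record(class, seqs, m, n)
    data.frame(m = r$m, angle = r$angle, u = r$vector[1], v = r$vector[2])
  })
  do.call(rbind, rows)
}

#' Sum of neural records: the represented endpoint
#'
#' Summing the records of steps 1..n gives the final represented home
#' vector.  With linear update noise disabled this equals, to machine
#' precision, the endpoint of the sequential simulation driven by the same
#' noise realization ([run_pi()] with matched `noise`), which is the
#' module's central consistency oracle.
#'
#' @inheritParams nr_record
#' @return numeric length-2 vector `c(U, V)`.
#' @export
reconstruct_endpoint <- function(class, seqs, n = seqs$n) {
  recs <- nr_records(class, seqs, n)
  c(sum(recs$u), sum(recs$v))
}

#' Renumber neural records in reverse temporal order
#'
#' Reversing the step numbering (step n becomes step 1, and so on) turns
#' the backward-accumulating record of an egocentric static representation
#' into a forward-accumulating walk: the angular increments of the
#' reversed records are fresh `-delta` terms, i.e. an idiothetic directed
#' walk driven by the reversed, negated input-error sequence.  The summed
#' endpoint is invariant.
#'
#' @param records a data.frame from [nr_records()].
#' @return the records with rows reversed and `m` renumbered `1..n`.
#' @export
renumber_reversed <- function(records) {
  stopifnot(is.data.frame(records), all(c("m", "angle", "u", "v") %in%
                                          names(records)))
  out <- records[rev(seq_len(nrow(records))), , drop = FALSE]
  out$m <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write neural records as CSV
#'
#' Layout `m,angle,u,v` for one (class, n) record set.
#'
#' @param records a data.frame from [nr_records()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
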