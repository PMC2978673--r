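#' Mean cosine contraction of a Gaussian angular error
#'
#' `E[cos(delta)] = exp(-sd^2 / 2)` for `delta ~ N(0, sd^2)`: the per-step
#' contraction factor of directed-walk means.  The average trajectory of an
#' allothetic directed walk has the shape of the ideal one, shrunk by this
#' constant.
#'
#' @param delta_sd angular standard deviation, radians, >= 0.
#' @return a value in (0, 1].
#' @export
expected_cos <- function(delta_sd) {
  stopifnot(delta_sd >= 0)
  exp(-delta_sd^2 / 2)
}

#' Mean endpoint of an allothetic directed walk
#'
#' With fresh per-step heading errors the mean displacement after n steps
#' is `(n * L * c, 0)` with `c = expected_cos(delta_sd)`.
#'
#' @param n number of steps, >= 1.
#' @param L step length.
#' @param delta_sd per-step heading error sd, radians.
#' @return numeric length-2 vector.
#' @export
adw_mean_endpoint <- function(n, L = 1, delta_sd = pi / 36) {
  stopifnot(n >= 1)
  c(n * L * expected_cos(delta_sd), 0)
}

#' Finite mean-displacement limit of an idiothetic directed walk
#'
#' Accumulating heading errors make the expected along-axis displacement
#' converge: under the step-1-carries-error convention, mean X after n
#' steps is `L * (c + c^2 + .. + c^n)`, with limit `L * c / (1 - c)`,
#' `c = expected_cos(delta_sd)`.  However many steps are taken, the mean
#' position stays within this radius of home.
#'
#' @param L step length.
#' @param delta_sd per-step turn error sd, radians; must be > 0 (at zero
#'   noise the mean displacement grows without bound).
#' @return the limiting mean along-axis displacement, length units.
#' @export
idw_limit <- function(L = 1, delta_sd = pi / 36) {
  if (delta_sd <= 0) {
    stop("idw_limit: mean displacement diverges at delta_sd = 0 ",
         "(no finite limit)")
  }
  cc <- expected_cos(delta_sd)
  L * cc / (1 - cc)
}

#' Sample directed-walk endpoints
#'
#' Vectorized endpoint sampler for the three reference walks: `"adw"`
#' (fresh Gaussian heading errors), `"idw"` (accumulating Gaussian turn
#' errors) and `"rw"` (a pure random walk: iid uniform headings, fixed
#' step length).
#'
#' @param kind `"adw"`, `"idw"` or `"rw"`.
#' @param n_paths number of independent paths.
#' @param n steps per path.
#' @param L step length.
#' @param delta_sd angular error sd (ignored for `"rw"`).
#' @param rng an [make_rng()] stream or integer seed.
#' @return an `n_paths` x 2 matrix of endpoints.
#' @export
sample_dw_endpoints <- function(kind = c("adw", "idw", "rw"), n_paths, n,
                                L = 1, delta_sd = pi / 36, rng = 1) {
  kind <- match.arg(kind)
  rng <- .as_rng(rng, paste0("endpoints-", kind))
  H <- switch(kind,
    adw = matrix(rng_normal(rng, n * n_paths, delta_sd), n, n_paths),
    idw = apply(matrix(rng_normal(rng, n * n_paths, delta_sd),
                       n, n_paths), 2, cumsum),
    rw = matrix(rng_uniform(rng, n * n_paths, -pi, pi), n, n_paths))
  if (n == 1) H <- matrix(H, 1, n_paths)
  cbind(x = colSums(L * cos(H)), y = colSums(L * sin(H)))
}

#' Along-axis displacement of idiothetic walks at checkpoints
#'
#' Simulates `n_paths` idiothetic directed walks up to
#' `max(checkpoints)` steps (chunked over paths to bound memory) and
#' returns the along-axis (X) displacement of every path at each
#' checkpoint, for Monte-Carlo checks of the finite mean-displacement
#' limit and its saturation.
#'
#' @param n_paths number of paths.
#' @param checkpoints increasing vector of step counts.
#' @param L step length.
#' @param delta_sd per-step turn error sd, radians.
#' @param rng an [make_rng()] stream or integer seed.
#' @param chunk paths simulated per chunk.
#' @return an `n_paths` x `length(checkpoints)` matrix.
#' @export
idw_checkpoint_x <- function(n_paths, checkpoints, L = 1,
                             delta_sd = pi / 36, rng = 1, chunk = 1000) {
  stopifnot(all(diff(checkpoints) > 0), all(checkpoints >= 1))
  rng <- .as_rng(rng, "idw-checkpoints")
  n <- max(checkpoints)
  out <- matrix(NA_real_, n_paths, length(checkpoints))
  done <- 0
  while (done < n_paths) {
    p <- min(chunk, n_paths - done)
    H <- apply(matrix(rng_normal(rng, n * p, delta_sd), n, p), 2, cumsum)
    X <- apply(L * cos(H), 2, cumsum)
    out[done + seq_len(p), ] <- t(X[checkpoints, , drop = FALSE])
    done <- done + p
  }
  out
}

#' Endpoint variance ordering of the three walk types
#'
#' Estimates the total endpoint variance (trace of the endpoint
#' covariance, a rotation-invariant scalar) of idiothetic walks, pure
#' random walks and allothetic walks at the same step count and step
#' length, with bootstrap confidence intervals, and reports whether the
#' strict ordering IDW > RW > ADW holds with non-overlapping intervals.
#'
#' @param n steps per path.
#' @param L step length.
#' @param delta_sd angular error sd for the directed walks, radians.
#' @param n_paths Monte-Carlo paths per walk type.
#' @param rng an [make_rng()] stream or integer seed.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return a list with per-type variances `var_idw`, `var_rw`, `var_adw`,
#'   a `ci` matrix (rows idw/rw/adw), and logical `pass`.
#' @export
variance_ordering <- function(n, L = 1, delta_sd = pi / 36,
                              n_paths = 10000, rng = 1, n_boot = 200,
                              conf = 0.95) {
  rng <- .as_rng(rng, "variance-ordering")
  kinds <- c("idw", "rw", "adw")
  ends <- lapply(kinds, function(k)
    sample_dw_endpoints(k, n_paths, n, L, delta_sd, rng))
  names(ends) <- kinds
  tr_cov <- function(e) sum(diag(stats::cov(e)))
  vars <- vapply(ends, tr_cov, numeric(1))
  boot_idx <- matrix(
    ceiling(rng_uniform(rng, n_boot * n_paths, 0, 1) * n_paths),
    n_boot, n_paths)
  ci <- t(vapply(kinds, function(k) {
    reps <- vapply(seq_len(n_boot), function(b)
      tr_cov(ends[[k]][boot_idx[b, ], , drop = FALSE]), numeric(1))
    stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  }, numeric(2)))
  dimnames(ci) <- list(kinds, c("lower", "upper"))
  pass <- ci["idw", "lower"] > ci["rw", "upper"] &&
    ci["rw", "lower"] > ci["adw", "upper"]
  list(var_idw = vars[["idw"]], var_rw = vars[["rw"]],
       var_adw = vars[["adw"]], ci = ci, pass = pass)
}

#' Sample representational endpoints from closed-form neural records
#'
#' Draws independent noise sequences for `n_paths` journeys along a
#' straight physical walk and returns the represented endpoint of each
#' journey, computed from the closed-form record angles of the chosen
#' class (not from sequential simulation) — the cheap, independent route
#' for distributional comparisons against real-space directed walks.
#'
#' @param class a record class, see [nr_record()].
#' @param n_paths number of journeys.
#' @param n steps per journey.
#' @param delta_sd input noise sd, radians.
#' @param eps_angular_sd angular update noise sd, radians.
#' @param L step length.
#' @param rng an [make_rng()] stream or integer seed.
#' @return an `n_paths` x 2 matrix of represented endpoints.
#' @export
sample_record_endpoints <- function(class, n_paths, n,
                                    delta_sd = pi / 36,
                                    eps_angular_sd = pi / 36, L = 1,
                                    rng = 1) {
  class <- match.arg(class, .record_classes)
  rng <- .as_rng(rng, paste0("records-", class))
  D <- matrix(rng_normal(rng, n * n_paths, delta_sd), n, n_paths)
  E <- matrix(rng_normal(rng, n * n_paths, eps_angular_sd), n, n_paths)
  rev_cumsum <- function(M) {
    apply(M[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  }
  A <- switch(class,
    esvr = -rev_cumsum(D),
    advr = rev_cumsum(E),
    edvr = rev_cumsum(E - D),
    asvr = D,
    asvr_idiothetic = apply(D, 2, cumsum))
  if (n == 1) A <- matrix(A, 1, n_paths)
  cbind(x = colSums(L * cos(A)), y = colSums(L * sin(A)))
}

#' Ensemble home-vector error curves
#'
#' Runs several representation classes over the same set of ground-truth
#' turning walks (shared path stream; per-model independent noise
#' streams) and returns per-step mean positional error and its standard
#' error for every model, together with the mean radial distance R of the
#' true paths and per-model endpoint moments.
#'
#' @param models character vector from `"ac"`, `"ap"`, `"ec"`, `"ep"`,
#'   `"ring"`.
#' @param spec a [noise_spec()]; `input_mode` is chosen per model
#'   (`"compass"` for heading-input models, `"direct_rotation"` for
#'   egocentric models) unless `spec$input_mode` is
#'   `"compass_differenced"`, which is then used for egocentric models.
#' @param n_paths number of shared true paths.
#' @param n_steps steps per path.
#' @param step_length step length L (= Lambda).
#' @param turn_sd sd of the Gaussian random turns of the true paths,
#'   radians.
#' @param seed integer master seed; all streams derive from it.
#' @param n_units ring size if `"ring"` is among the models.
#' @return an object of class `ensemble_curves`: a list with `curves`
#'   (data.frame `step`, `model`, `mean_err`, `se`, `mean_xhat` — the mean
#'   decoded along-axis displacement, used for saturation checks on
#'   straight true walks), `mean_R` (length
#'   `n_steps`), `endpoints` (per-model list with `mean` and `cov` of the
#'   decoded endpoint), and the configuration echo.
#' @export
ensemble_hv_error <- function(models = c("ap", "ep", "ac", "ec"),
                              spec = noise_spec(), n_paths = 1000,
                              n_steps = 1000, step_length = 1,
                              turn_sd = 0.1, seed = 1, n_units = 16) {
  stopifnot(all(models %in% c("ac", "ap", "ec", "ep", "ring")),
            n_paths >= 1, n_steps >= 1)
  path_rng <- make_rng(seed, "path-turns")
  n <- n_steps; P <- n_paths; L <- step_length
  Turns <- matrix(rng_normal(path_rng, n * P, turn_sd), n, P)
  H <- apply(Turns, 2, cumsum)
  if (n == 1) H <- matrix(H, 1, P)
  X <- apply(L * cos(H), 2, cumsum)
  Y <- apply(L * sin(H), 2, cumsum)
  if (n == 1) { X <- matrix(X, 1, P); Y <- matrix(Y, 1, P) }
  R <- sqrt(X^2 + Y^2)
  mean_R <- rowMeans(R)

  curves <- list()
  endpoints <- list()
  for (model in models) {
    err_xy <- .ensemble_model_positions(model, H, Turns, X, Y, L, spec,
                                        seed, n_units)
    err <- sqrt((err_xy$x - X)^2 + (err_xy$y - Y)^2)
    mean_err <- rowMeans(err)
    se <- apply(err, 1, stats::sd) / sqrt(P)
    curves[[model]] <- data.frame(step = seq_len(n), model = model,
                                  mean_err = mean_err, se = se,
                                  mean_xhat = rowMeans(err_xy$x))
    ep <- cbind(err_xy$x[n, ], err_xy$y[n, ])
    endpoints[[model]] <- list(mean = colMeans(ep), cov = stats::cov(ep))
  }
  structure(
    list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
         mean_R = mean_R, endpoints = endpoints,
         config = list(models = models, n_paths = P, n_steps = n,
                       step_length = L, turn_sd = turn_sd, seed = seed,
                       n_units = n_units,
                       delta_sd = spec$delta_sd,
                       eps_angular_sd = spec$eps_angular_sd,
                       eps_linear_sd = spec$eps_linear_sd,
                       input_mode = spec$input_mode)),
    class = "ensemble_curves")
}

# decoded allocentric positions (n x P matrices x, y) of one model run
# over shared true headings H; vectorized across paths
.ensemble_model_positions <- function(model, H, Turns, X, Y, L, spec,
                                      seed, n_units) {
  n <- nrow(H); P <- ncol(H)
  delta_rng <- make_rng(seed, paste0("delta-", model))
  eps_rng <- make_rng(seed, paste0("eps-", model))
  D <- matrix(rng_normal(delta_rng, n * P, spec$delta_sd), n, P)
  el <- spec$eps_linear_sd; ea <- spec$eps_angular_sd

  if (model %in% c("ac", "ring", "ap")) {
    TH <- if (spec$input_mode == "direct_rotation") {
      A <- apply(Turns + D, 2, cumsum)
      if (n == 1) matrix(A, 1, P) else A
    } else H + D
  }

  if (model == "ac") {
    EU <- matrix(rng_normal(eps_rng, n * P, el), n, P)
    EV <- matrix(rng_normal(eps_rng, n * P, el), n, P)
    x <- apply(L * cos(TH) + EU, 2, cumsum)
    y <- apply(L * sin(TH) + EV, 2, cumsum)
    if (n == 1) { x <- matrix(x, 1, P); y <- matrix(y, 1, P) }
    return(list(x = x, y = y))
  }

  if (model == "ring") {
    dirs <- ring_state(n_units)$preferred_dirs
    Sx <- matrix(0, n, P); Sy <- matrix(0, n, P)
    Cmat <- cbind(cos(dirs), sin(dirs))
    G <- solve(crossprod(Cmat)) # 2x2; LS decode of moduli onto harmonics
    Mx <- matrix(0, n, P); My <- matrix(0, n, P)
    for (i in seq_len(n_units)) {
      Ei <- matrix(rng_normal(eps_rng, n * P, el), n, P)
      Mi <- apply(L * cos(TH - dirs[i]) + Ei, 2, cumsum)
      if (n == 1) Mi <- matrix(Mi, 1, P)
      Mx <- Mx + Mi * Cmat[i, 1]
      My <- My + Mi * Cmat[i, 2]
    }
    x <- G[1, 1] * Mx + G[1, 2] * My
    y <- G[2, 1] * Mx + G[2, 2] * My
    return(list(x = x, y = y))
  }

  if (model == "ap") {
    ER <- matrix(rng_normal(eps_rng, n * P, el), n, P)
    EP <- matrix(rng_normal(eps_rng, n * P, ea), n, P)
    r <- numeric(P); phi <- numeric(P)
    x <- matrix(0, n, P); y <- matrix(0, n, P)
    for (k in seq_len(n)) {
      px <- r * cos(phi) + L * cos(TH[k, ])
      py <- r * sin(phi) + L * sin(TH[k, ])
      r <- pmax(sqrt(px^2 + py^2) + ER[k, ], 0)
      phi <- atan2(py, px) + EP[k, ]
      x[k, ] <- r * cos(phi); y[k, ] <- r * sin(phi)
    }
    return(list(x = x, y = y))
  }

  # egocentric models: end-of-step rotation readings
  turn_out <- rbind(Turns[-1, , drop = FALSE], rep(0, P))
  H_faced <- rbind(H[-1, , drop = FALSE], H[n, ])
  Rot <- if (spec$input_mode == "compass_differenced") {
    D0 <- rng_normal(delta_rng, P, spec$delta_sd) # initial reading error
    readings <- rbind(H[1, ] + D0, H_faced + D)
    apply(readings, 2, diff)
  } else {
    turn_out + D
  }
  if (n == 1) Rot <- matrix(Rot, 1, P)

  if (model == "ec") {
    EU <- matrix(rng_normal(eps_rng, n * P, el), n, P)
    EV <- matrix(rng_normal(eps_rng, n * P, el), n, P)
    u <- numeric(P); v <- numeric(P)
    x <- matrix(0, n, P); y <- matrix(0, n, P)
    for (k in seq_len(n)) {
      u <- u - L + EU[k, ]
      v <- v + EV[k, ]
      cu <- cos(Rot[k, ]); su <- sin(Rot[k, ])
      u_new <- cu * u + su * v
      v <- -su * u + cu * v
      u <- u_new
      ch <- cos(H_faced[k, ]); sh <- sin(H_faced[k, ])
      x[k, ] <- -(ch * u - sh * v)
      y[k, ] <- -(sh * u + ch * v)
    }
    return(list(x = x, y = y))
  }

  # ep
  ER <- matrix(rng_normal(eps_rng, n * P, el), n, P)
  EP <- matrix(rng_normal(eps_rng, n * P, ea), n, P)
  r <- numeric(P); phi <- numeric(P)
  x <- matrix(0, n, P); y <- matrix(0, n, P)
  for (k in seq_len(n)) {
    px <- r * cos(phi) - L
    py <- r * sin(phi)
    r <- pmax(sqrt(px^2 + py^2) + ER[k, ], 0)
    phi <- atan2(py, px) + EP[k, ]
    phi <- phi - Rot[k, ]
    u <- r * cos(phi); v <- r * sin(phi)
    ch <- cos(H_faced[k, ]); sh <- sin(H_faced[k, ])
    x[k, ] <- -(ch * u - sh * v)
    y[k, ] <- -(sh * u + ch * v)
  }
  list(x = x, y = y)
}

#' @export
print.ensemble_curves <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ensemble_curves models=%s n_paths=%d n_steps=%d>\n",
              paste(cfg$models, collapse = ","), cfg$n_paths, cfg$n_steps))
  last <- x$curves[x$curves$step == cfg$n_steps, ]
  for (i in seq_len(nrow(last))) {
    cat(sprintf("  %-4s mean error at step %d: %8.3f (SE %.3f)\n",
                last$model[i], cfg$n_steps, last$mean_err[i], last$se[i]))
  }
  cat(sprintf("  mean radial distance R at step %d: %.3f\n",
              cfg$n_steps, x$mean_R[cfg$n_steps]))
  invisible(x)
}

#' Write ensemble curves as CSV / JSON summary
#'
#' The CSV layout is `step,model,mean_err,se,mean_R` (the true-path mean
#' radial distance repeated for each model's rows).  The JSON summary
#' echoes the configuration (including the seed) plus final-step values.
#'
#' @param curves an `ensemble_curves` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "ensemble_curves"))
  df <- curves$curves
  df$mean_R <- curves$mean_R[df$step]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
write_curves_summary_json <- function(curves, path) {
  stopifnot(inherits(curves, "ensemble_curves"))
  n <- curves$config$n_steps
  last <- curves$curves[curves$curves$step == n, ]
  summary <- list(
    config = curves$config,
    final_step = n,
    final_mean_err = stats::setNames(as.list(last$mean_err), last$model),
    final_mean_R = curves$mean_R[n]
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Log-log growth exponent of a positive curve
#'
#' Least-squares slope of `log(value)` on `log(step)` over a step window;
#' used to classify error growth (an allothetic-like error curve grows
#' about as sqrt(n), exponent near 0.5; linear growth has exponent 1).
#'
#' @param values positive numeric vector indexed by step.
#' @param steps the steps to fit over (default: all).
#' @return the fitted exponent (slope).
#' @export
growth_exponent <- function(values, steps = seq_along(values)) {
  stopifnot(all(values[steps] > 0))
  stats::coef(stats::lm(log(values[steps]) ~ log(steps)))[[2]]
}
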