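#' Experiment configuration
#'
#' Bundles every knob of an ensemble experiment.  Defaults are the
#' standard noisy-path-integration conditions: 1000 true paths of 1000
#' steps of length 1, Gaussian random turns with sd 0.1 rad between
#' successive steps, input noise delta and update noise epsilon both with
#' sd pi/36 (5 degrees, or the equivalent in length units for linear
#' parameters).
#'
#' @param n_paths number of true paths, >= 1.
#' @param n_steps steps per path, >= 1.
#' @param step_length step length L (= Lambda).
#' @param turn_sd true-path turn sd, radians.
#' @param delta_sd input noise sd, radians.
#' @param eps_angular_sd angular update noise sd, radians.
#' @param eps_linear_sd linear update noise sd, length units.
#' @param input_mode see [noise_spec()].
#' @param models representation classes to run.
#' @param n_units ring size if `"ring"` is included.
#' @param seed master seed.
#' @param out_dir output directory for CSV/JSON products (`NULL`: do not
#'   write).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_paths = 1000, n_steps = 1000,
                              step_length = 1, turn_sd = 0.1,
                              delta_sd = pi / 36,
                              eps_angular_sd = pi / 36,
                              eps_linear_sd = pi / 36,
                              input_mode = "compass",
                              models = c("ap", "ep", "ac", "ec"),
                              n_units = 16, seed = 1, out_dir = NULL) {
  stopifnot(n_paths >= 1, n_steps >= 1, step_length > 0)
  bad <- setdiff(models, c("ac", "ap", "ec", "ep", "ring"))
  if (length(bad) > 0) {
    stop("unknown model(s) ", paste(bad, collapse = ", "),
         "; valid models are ac, ap, ec, ep, ring")
  }
  structure(
    list(n_paths = as.integer(n_paths), n_steps = as.integer(n_steps),
         step_length = step_length, turn_sd = turn_sd, delta_sd = delta_sd,
         eps_angular_sd = eps_angular_sd, eps_linear_sd = eps_linear_sd,
         input_mode = input_mode, models = models,
         n_units = as.integer(n_units), seed = as.integer(seed),
         out_dir = out_dir),
    class = "experiment_config")
}

.config_spec <- function(config) {
  noise_spec(delta_sd = config$delta_sd,
             eps_angular_sd = config$eps_angular_sd,
             eps_linear_sd = config$eps_linear_sd,
             input_mode = config$input_mode)
}

#' Reproduce the four-class noisy path-integration comparison
#'
#' Runs every configured representation class over the same set of random
#' turning walks and collects the per-step mean home-vector error curves,
#' the mean radial distance of the true paths, and one example trace per
#' model (the single-path overlay analogue).  With `out_dir` set, writes
#' `curves.csv`, `summary.json` and one `trace_<model>.csv` per model.
#'
#' @param config an [experiment_config()].
#' @return a list with `curves` (an [ensemble_hv_error()] result) and
#'   `traces` (named list of single-path `hv_trace` objects).
#' @export
run_fig4 <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- .config_spec(config)
  curves <- ensemble_hv_error(models = config$models, spec = spec,
                              n_paths = config$n_paths,
                              n_steps = config$n_steps,
                              step_length = config$step_length,
                              turn_sd = config$turn_sd,
                              seed = config$seed,
                              n_units = config$n_units)
  example <- turning_walk(config$n_steps, config$step_length,
                          config$turn_sd,
                          make_rng(config$seed, "example-path"))
  traces <- lapply(stats::setNames(config$models, config$models),
                   function(m) {
    mspec <- spec
    if (m %in% c("ec", "ep") && spec$input_mode == "compass") {
      mspec$input_mode <- "direct_rotation"
    }
    run_pi(example, m, mspec,
           rng = list(delta = make_rng(config$seed, paste0("trace-delta-", m)),
                      eps = make_rng(config$seed, paste0("trace-eps-", m))),
           n_units = config$n_units)
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_curves_csv(curves, file.path(config$out_dir, "curves.csv"))
    write_curves_summary_json(curves,
                              file.path(config$out_dir, "summary.json"))
    for (m in names(traces)) {
      write_hv_trace_csv(traces[[m]],
                         file.path(config$out_dir,
                                   sprintf("trace_%s.csv", m)))
    }
  }
  list(curves = curves, traces = traces)
}

#' Small deterministic worked-example bundle
#'
#' A self-contained three-step bundle for tests and demonstrations: a
#' 3-step straight walk, fixed delta/epsilon sequences drawn from the
#' seed's named streams, the per-class closed-form neural records, and
#' the record-sum endpoints, all computed (not hard-coded) at generation
#' time.
#'
#' @param seed integer seed.
#' @return a list with `trajectory`, `delta`, `eps_angular`,
#'   `step_lengths`, `records` (per class), `endpoints` (per class).
#' @export
make_fixture <- function(seed = 0) {
  traj <- straight_walk(3, 1)
  delta <- rng_normal(make_rng(seed, "fixture-delta"), 3, pi / 36)
  eps <- rng_normal(make_rng(seed, "fixture-eps"), 3, pi / 36)
  seqs <- error_sequences(delta, eps, step_lengths = 1)
  classes <- c("esvr", "advr", "edvr", "asvr", "asvr_idiothetic")
  records <- lapply(stats::setNames(classes, classes),
                    function(cl) nr_records(cl, seqs))
  endpoints <- lapply(stats::setNames(classes, classes),
                      function(cl) reconstruct_endpoint(cl, seqs))
  list(trajectory = traj, delta = delta, eps_angular = eps,
       step_lengths = seqs$step_lengths, records = records,
       endpoints = endpoints, seed = seed)
}
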