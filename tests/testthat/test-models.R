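# sensing, per-class updates, decoding, and run_pi invariants

test_that("sense_heading adds fresh wrapped compass noise", {
  spec <- noise_spec(delta_sd = pi / 36)
  expect_equal(
    sense_heading(0.3, noise_spec(delta_sd = 0), make_rng(1, "d")), 0.3)
  draws <- sense_heading(rep(0, 10000), spec, make_rng(2, "d"))
  expect_lt(abs(stats::sd(draws) - pi / 36) / (pi / 36), 0.05)
  near_pi <- sense_heading(rep(pi, 200), spec, make_rng(3, "d"))
  expect_true(all(near_pi > -pi & near_pi <= pi))
  expect_error(
    sense_heading(0, noise_spec(input_mode = "direct_rotation"),
                  make_rng(1, "d")),
    "compass")
})

test_that("sense_rotation: direct mode is fresh noise, compass differencing
           telescopes", {
  z <- noise_spec(delta_sd = 0, input_mode = "direct_rotation")
  expect_equal(sense_rotation(0.2, z, make_rng(1, "d"))$measurement, 0.2)
  spec <- noise_spec(delta_sd = pi / 36, input_mode = "direct_rotation")
  rng <- make_rng(4, "d")
  ms <- vapply(1:5000, function(i) sense_rotation(0, spec, rng)$measurement,
               numeric(1))
  expect_lt(abs(stats::sd(ms) - pi / 36) / (pi / 36), 0.05)
  # compass-differenced on a straight walk: errors telescope to dn - d0
  spec2 <- noise_spec(delta_sd = 0.05, input_mode = "compass_differenced")
  rng2 <- make_rng(5, "d")
  prev <- NULL; total <- 0; first_err <- NULL; last_err <- NULL
  for (k in 1:200) {
    s <- sense_rotation(0, spec2, rng2, prev_compass_error = prev)
    if (is.null(prev)) {
      # reconstruct delta_0: measurement = delta_1 - delta_0
      first_err <- s$compass_error - s$measurement
    }
    total <- total + s$measurement
    prev <- s$compass_error
    last_err <- s$compass_error
  }
  expect_equal(total, last_err - first_err, tolerance = 1e-12)
  expect_error(sense_rotation(0, noise_spec(), make_rng(1, "d")),
               "direct_rotation")
})

test_that("single-step updates obey their geometry", {
  z <- noise_spec(0, 0, 0)
  r <- make_rng(1, "e")
  # AC
  s <- update_ac(ac_state(0, 0), step_input(1, measured_heading = 0), z, r)
  expect_equal(c(s$u, s$v), c(1, 0))
  s <- update_ac(ac_state(0, 0), step_input(2, measured_heading = pi / 2),
                 z, r)
  expect_equal(c(s$u, s$v), c(0, 2))
  s <- ac_state()
  for (k in 1:3) s <- update_ac(s, step_input(1, measured_heading = 0), z, r)
  expect_equal(c(s$u, s$v), c(3, 0))
  expect_error(update_ac(ac_state(), step_input(1), z, r), "measured_heading")
  # AP from home
  s <- update_ap(ap_state(), step_input(1, measured_heading = 0), z, r)
  expect_equal(c(s$r, s$phi), c(1, 0))
  # EC: one forward step from home puts home directly behind
  s <- update_ec(ec_state(), step_input(1, measured_rotation = 0), z, r)
  expect_equal(c(s$u_prime, s$v_prime), c(-1, 0))
  # EC frame geometry: left turn, home behind -> home on the left (+V')
  s <- update_ec(ec_state(-1, 0), step_input(0, measured_rotation = pi / 2),
                 z, r)
  expect_equal(c(s$u_prime, s$v_prime), c(0, 1))
  # EP from home: home behind means bearing pi
  s <- update_ep(ep_state(), step_input(1, measured_rotation = 0), z, r)
  expect_equal(c(s$r_prime, s$phi_prime), c(1, pi))
  # ring with N = 2 (dirs 0, pi/2) is exactly AC
  s <- ring_state(2)
  for (k in 1:3) {
    s <- update_ring(s, step_input(1, measured_heading = 0.4), z, r)
  }
  expect_equal(s$moduli, 3 * c(cos(0.4), cos(0.4 - pi / 2)))
  expect_equal(decode_hv(s), 3 * c(cos(0.4), sin(0.4)))
  expect_error(ring_state(1), "n_units")
})

test_that("decode_hv reconciles the frame conventions", {
  expect_equal(decode_hv(ac_state(3, 4)), c(3, 4))
  expect_equal(decode_hv(ap_state(5, pi / 2)), c(0, 5),
               tolerance = 1e-12)
  expect_equal(decode_hv(ec_state(-1, 0), true_heading = 0), c(1, 0))
  # home one unit to the animal's left while it faces +Y: animal is at
  # home + one unit east
  expect_equal(decode_hv(ec_state(0, 1), true_heading = pi / 2), c(1, 0),
               tolerance = 1e-12)
  expect_equal(decode_hv(ep_state(2, pi), true_heading = 0), c(2, 0),
               tolerance = 1e-12)
  # ring N = 16 decodes an arbitrary noise-free walk exactly
  s <- ring_state(16)
  z <- noise_spec(0, 0, 0); r <- make_rng(1, "e")
  for (h in c(0.3, -1.2, 2.8)) {
    s <- update_ring(s, step_input(1.5, measured_heading = h), z, r)
  }
  truth <- 1.5 * c(sum(cos(c(0.3, -1.2, 2.8))), sum(sin(c(0.3, -1.2, 2.8))))
  expect_equal(decode_hv(s), truth, tolerance = 1e-9)
})

test_that("noise-free class equivalence: all five models decode the same HV
           on arbitrary trajectories", {
  zs <- list(ac = noise_spec(0, 0, 0), ap = noise_spec(0, 0, 0),
             ring = noise_spec(0, 0, 0),
             ec = noise_spec(0, 0, 0, input_mode = "direct_rotation"),
             ep = noise_spec(0, 0, 0, input_mode = "direct_rotation"))
  for (seed in 1:5) {
    tr <- real_trajectory(
      headings = cumsum(rng_normal(make_rng(seed, "eq"), 40, 0.5)),
      step_lengths = 0.5 + rng_uniform(make_rng(seed, "eqL"), 40))
    decs <- lapply(names(zs), function(m) {
      t <- run_pi(tr, m, zs[[m]], rng = seed)
      expect_lt(max(t$pos_error), 1e-9)
      cbind(t$x_hat, t$y_hat)
    })
    for (d in decs[-1]) expect_equal(d, decs[[1]], tolerance = 1e-9)
  }
})

test_that("angular update noise rotates the whole polar representation", {
  # applying eps_phi then decoding == decoding then rotating by eps_phi
  st <- ap_state(3, 0.7)
  eps <- 0.23
  rotated <- ap_state(st$r, st$phi + eps)
  d0 <- decode_hv(st); d1 <- decode_hv(rotated)
  R <- matrix(c(cos(eps), sin(eps), -sin(eps), cos(eps)), 2)
  expect_equal(d1, as.numeric(R %*% d0), tolerance = 1e-12)
})

test_that("positional error is frame-invariant (isometry)", {
  tr <- turning_walk(30, 1, 0.2, make_rng(6, "fr"))
  spec <- noise_spec(input_mode = "direct_rotation")
  t_ec <- run_pi(tr, "ec", spec, rng = 3)
  # recompute the error in the egocentric frame: home-estimate minus true
  # home position expressed in the animal's frame
  h_faced <- c(tr$headings[-1], tr$headings[tr$n_steps])
  for (k in c(5, 17, 30)) {
    hv_ego <- c(t_ec$u_prime[k + 1], t_ec$v_prime[k + 1])
    h <- h_faced[k]
    Rb <- matrix(c(cos(h), -sin(h), sin(h), cos(h)), 2, byrow = TRUE)
    true_home_ego <- as.numeric(t(Rb) %*% (-tr$positions[k + 1, ]))
    ego_err <- sqrt(sum((hv_ego - true_home_ego)^2))
    expect_equal(ego_err, t_ec$pos_error[k + 1], tolerance = 1e-9)
  }
})

test_that("matched input noise: EC diverges while AC stays bounded", {
  n <- 400
  sw <- straight_walk(n, 1)
  spec_ac <- noise_spec(delta_sd = pi / 18, eps_angular_sd = 0,
                        eps_linear_sd = 0)
  spec_ec <- noise_spec(delta_sd = pi / 18, eps_angular_sd = 0,
                        eps_linear_sd = 0, input_mode = "direct_rotation")
  errs <- sapply(1:40, function(seed) {
    c(ac = tail(run_pi(sw, "ac", spec_ac, rng = seed)$pos_error, 1),
      ec = tail(run_pi(sw, "ec", spec_ec, rng = seed)$pos_error, 1))
  })
  expect_gt(mean(errs["ec", ]), 5 * mean(errs["ac", ]))
})

test_that("run_pi traces are bit-reproducible and CSV export is stable", {
  tr <- turning_walk(50, 1, 0.1, make_rng(8, "rep"))
  t1 <- run_pi(tr, "ap", noise_spec(), rng = 21)
  t2 <- run_pi(tr, "ap", noise_spec(), rng = 21)
  expect_identical(t1, t2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hv_trace_csv(t1, path)
  df <- utils::read.csv(path)
  expect_identical(names(df),
                   c("step", "r", "phi", "x_hat", "y_hat", "pos_error"))
  expect_equal(nrow(df), 51)
  # incompatible input modes are rejected
  expect_error(run_pi(tr, "ec", noise_spec(input_mode = "compass"), 1),
               "heading-input")
  expect_error(
    run_pi(tr, "ac", noise_spec(input_mode = "compass_differenced"), 1),
    "rotation-input")
})
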