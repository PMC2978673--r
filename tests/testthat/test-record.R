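# closed-form neural records: hand expansions, brute-force bookkeeping
# oracle, sequential-simulation oracle, reversal renumbering

test_that("record angles match hand expansion and zero-noise reduction", {
  a <- 0.3; b <- -0.2
  seqs <- error_sequences(delta = c(a, b), eps_angular = c(0, 0))
  # egocentric static, n = 2: step-1 angle -(a+b), step-2 angle -b;
  # the incremental angle between the two is +a (the reversed-index -delta)
  r1 <- nr_record("esvr", seqs, 1); r2 <- nr_record("esvr", seqs, 2)
  expect_equal(r1$angle, -(a + b))
  expect_equal(r2$angle, -b)
  expect_equal(r1$angle - r2$angle, -a)
  # allocentric static: records depend only on own-step delta
  expect_equal(nr_record("asvr", seqs, 1)$angle, a)
  expect_equal(nr_record("asvr", seqs, 2)$angle, b)
  # all-zero errors: every class records the pristine step
  z <- error_sequences(delta = rep(0, 4), step_lengths = c(1, 2, 3, 4))
  for (cl in c("esvr", "advr", "edvr", "asvr", "asvr_idiothetic")) {
    expect_equal(nr_record(cl, z, 3)$vector, c(3, 0))
  }
  expect_error(nr_record("esvr", seqs, 3), "indices")
  expect_error(nr_record("xsvr", seqs, 1))
})

test_that("closed-form records equal brute-force vector bookkeeping", {
  rng <- make_rng(17, "brute")
  for (cl in c("esvr", "advr", "edvr", "asvr", "asvr_idiothetic")) {
    for (rep in 1:3) {
      n <- 3 + rep * 4
      delta <- rng_normal(rng, n, 0.3)
      eps <- rng_normal(rng, n, 0.2)
      lam <- 0.5 + rng_uniform(rng, n)
      seqs <- error_sequences(delta, eps, lam)
      got <- as.matrix(nr_records(cl, seqs)[, c("u", "v")])
      want <- brute_records(cl, delta, eps, lam)
      expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("asvr records never couple across steps (finite differences)", {
  rng <- make_rng(19, "fd")
  n <- 6
  delta <- rng_normal(rng, n, 0.2)
  seqs <- error_sequences(delta)
  base <- as.matrix(nr_records("asvr", seqs)[, c("u", "v")])
  for (k in seq_len(n)) {
    d2 <- delta; d2[k] <- d2[k] + 1e-4
    pert <- as.matrix(nr_records("asvr", error_sequences(d2))[, c("u", "v")])
    changed <- rowSums(abs(pert - base)) > 0
    expect_equal(which(changed), k)
  }
})

test_that("record sums reproduce the sequential simulation endpoint for
           every class (matched noise, linear update noise off)", {
  rng <- make_rng(23, "oracle")
  cases <- list(
    esvr = list(model = "ec", mode = "direct_rotation",
                use = c(d = TRUE, e = FALSE)),
    advr = list(model = "ap", mode = "compass",
                use = c(d = FALSE, e = TRUE)),
    edvr = list(model = "ep", mode = "direct_rotation",
                use = c(d = TRUE, e = TRUE)),
    asvr = list(model = "ac", mode = "compass",
                use = c(d = TRUE, e = FALSE)),
    asvr_idiothetic = list(model = "ac", mode = "direct_rotation",
                           use = c(d = TRUE, e = FALSE)))
  for (cl in names(cases)) {
    cs <- cases[[cl]]
    for (rep in 1:6) {
      n <- 2 + floor(rng_uniform(rng, 1, 0, 1) * 30)
      delta <- if (cs$use["d"]) rng_normal(rng, n, 0.25) else rep(0, n)
      eps <- if (cs$use["e"]) rng_normal(rng, n, 0.2) else rep(0, n)
      lam <- 0.5 + rng_uniform(rng, n)
      sw <- real_trajectory(rep(0, n), lam)
      spec <- noise_spec(delta_sd = 1, eps_angular_sd = 1,
                         eps_linear_sd = 0, input_mode = cs$mode)
      trace <- run_pi(sw, cs$model, spec, rng = 1,
                      noise = list(delta = delta, eps_angular = eps,
                                   eps_linear = matrix(0, n, 2)))
      seq_end <- c(trace$x_hat[n + 1], trace$y_hat[n + 1])
      rec_end <- reconstruct_endpoint(cl, error_sequences(delta, eps, lam))
      expect_lt(max(abs(seq_end - rec_end)), 1e-9,
                label = paste(cl, "rep", rep))
    }
  }
})

test_that("reverse renumbering turns the egocentric record into a forward
           IDW and leaves the endpoint invariant", {
  rng <- make_rng(29, "rev")
  n <- 12
  delta <- rng_normal(rng, n, 0.3)
  seqs <- error_sequences(delta)
  recs <- nr_records("esvr", seqs)
  rev_recs <- renumber_reversed(recs)
  # n = 1 is the identity
  one <- nr_records("esvr", error_sequences(delta[1]))
  expect_equal(renumber_reversed(one), one)
  # reversed angles accumulate fresh -delta terms forward:
  # angle_j = -(delta_n + ... + delta_{n+1-j})
  expect_equal(rev_recs$angle, cumsum(-rev(delta)), tolerance = 1e-12)
  # pathwise identity with an IDW in representational space driven by the
  # reversed, negated delta sequence
  idw_heads <- cumsum(-rev(delta))
  expect_equal(rev_recs$u, cos(idw_heads), tolerance = 1e-12)
  expect_equal(rev_recs$v, sin(idw_heads), tolerance = 1e-12)
  # endpoint invariance under renumbering
  expect_equal(c(sum(rev_recs$u), sum(rev_recs$v)),
               reconstruct_endpoint("esvr", seqs), tolerance = 1e-12)
})

test_that("class-to-directed-walk mapping holds distributionally
           (small-scale version)", {
  # representational endpoints on a straight walk vs the matched real-space
  # walk generator; full-scale version in the acceptance suite
  n <- 60; P <- 800; sd_d <- 0.12; sd_e <- 0.09
  pairs <- list(
    esvr = list(kind = "idw", sd = sd_d),
    advr = list(kind = "idw", sd = sd_e),
    edvr = list(kind = "idw", sd = sqrt(sd_d^2 + sd_e^2)),
    asvr = list(kind = "adw", sd = sd_d),
    asvr_idiothetic = list(kind = "idw", sd = sd_d))
  for (cl in names(pairs)) {
    rec <- sample_record_endpoints(cl, P, n, delta_sd = sd_d,
                                   eps_angular_sd = sd_e,
                                   rng = make_rng(31, paste0("r-", cl)))
    dw <- sample_dw_endpoints(pairs[[cl]]$kind, P, n, 1, pairs[[cl]]$sd,
                              make_rng(37, paste0("w-", cl)))
    expect_moments_match(rec, dw, label = cl)
  }
})

test_that("records CSV export has the documented layout", {
  seqs <- error_sequences(rng_normal(make_rng(3, "csv"), 5, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(nr_records("esvr", seqs), path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("m", "angle", "u", "v"))
  expect_equal(nrow(df), 5)
})
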