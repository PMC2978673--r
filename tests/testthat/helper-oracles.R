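# Independent oracles used across test files.

# E[cos(delta)], delta ~ N(0, sd^2), by adaptive quadrature (independent of
# the closed form exp(-sd^2/2))
quadrature_expected_cos <- function(sd) {
  if (sd == 0) return(1)
  stats::integrate(function(t) cos(t) * stats::dnorm(t, 0, sd),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

# Brute-force neural records by explicit vector bookkeeping: keep the list
# of per-step record vectors and apply each step's global rotation to every
# stored vector, per the geometric construction.  Independent of both the
# closed-form angle sums and the sequential state simulation.
brute_records <- function(class, delta, eps, lambda = rep(1, length(delta))) {
  n <- length(delta)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  vecs <- list()
  for (k in seq_len(n)) {
    entry_angle <- switch(class,
      esvr = 0, advr = 0, edvr = 0,
      asvr = delta[k],
      asvr_idiothetic = sum(delta[1:k]))
    vecs[[k]] <- lambda[k] * c(cos(entry_angle), sin(entry_angle))
    global <- switch(class,
      esvr = -delta[k], advr = eps[k], edvr = eps[k] - delta[k],
      asvr = 0, asvr_idiothetic = 0)
    if (global != 0) vecs <- lapply(vecs, rot, a = global)
  }
  do.call(rbind, vecs)
}

# two-sample 3-SE comparison of endpoint means and covariance entries
expect_moments_match <- function(a, b, label = "") {
  for (j in 1:2) {
    se <- sqrt(stats::var(a[, j]) / nrow(a) + stats::var(b[, j]) / nrow(b))
    expect_lt(abs(mean(a[, j]) - mean(b[, j])), 3 * se + 1e-12,
              label = paste(label, "mean", j))
  }
  # moment-based SEs for variances / covariance via 4th moments
  mom_se <- function(x, y) {
    z <- (x - mean(x)) * (y - mean(y))
    sqrt(stats::var(z) / length(z))
  }
  pairs <- list(c(1, 1), c(2, 2), c(1, 2))
  ca <- stats::cov(a); cb <- stats::cov(b)
  for (p in pairs) {
    se <- sqrt(mom_se(a[, p[1]], a[, p[2]])^2 +
               mom_se(b[, p[1]], b[, p[2]])^2)
    expect_lt(abs(ca[p[1], p[2]] - cb[p[1], p[2]]), 3 * se + 1e-12,
              label = paste(label, "cov", p[1], p[2]))
  }
}

# noise realization of zeros for run_pi matched-noise calls
zero_noise <- function(n, n_lin = 2, n_delta = n) {
  list(delta = rep(0, n_delta), eps_angular = rep(0, n),
       eps_linear = matrix(0, n, n_lin))
}
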