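test_that("proposal table normalizes and respects an absorbing regime chain", {
  dt <- 0.02
  theta <- slow_theta()
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  set.seed(11)
  for (i in 1:10) {
    xp <- random_state(theta, co)
    tab <- build_proposal_table(xp, rnorm(1), theta, co, dt)
    expect_equal(sum(tab$table), 1, tolerance = 1e-12)
    expect_true(all(tab$table >= 0))
    expect_gt(tab$z, 0)
  }
  # w01 = w10 = 0 from q_prev = 0: all mass stays in regime 0
  theta0 <- model_parameters(r0 = 1, r1 = 20, w01 = 0, w10 = 0, a_max = 1,
                             tau_r = 0.02, tau_d = 0.3, c0 = 0, sigma2 = 0.1,
                             sigma2_b = 0.1)
  xp <- latent_state(0, 0, c(0, 0), 0)
  tab <- build_proposal_table(xp, 0.2, theta0, co, dt)
  expect_equal(sum(tab$table[2, ]), 0)
  expect_equal(sum(tab$table[1, ]), 1, tolerance = 1e-12)
})

test_that("baseline full conditional has the stated limits and moments", {
  dt <- 0.01
  xp <- latent_state(0, 0, c(0, 0), b = 0.7)
  # sigma2_b*dt -> 0: mean -> b_prev
  th1 <- model_parameters(1, 1, 1, 1, 1, 0.02, 0.3, 0, 0.25, 1e-12)
  d1 <- sample_baseline(xp, c_t = 0.5, f = 2, th1, dt)
  expect_equal(attr(d1, "mu"), 0.7, tolerance = 1e-9)
  # sigma2 -> 0: mean -> f - c_t
  th2 <- model_parameters(1, 1, 1, 1, 1, 0.02, 0.3, 0, 1e-12, 4)
  d2 <- sample_baseline(xp, c_t = 0.5, f = 2, th2, dt)
  expect_equal(attr(d2, "mu"), 1.5, tolerance = 1e-9)
  # Monte Carlo moments match the conditional moments
  th <- model_parameters(1, 1, 1, 1, 1, 0.02, 0.3, 0, 0.04, 2)
  set.seed(2)
  dr <- sample_baseline(xp, c_t = 0.3, f = 1, th, dt, n = 1e5)
  expect_equal(mean(dr), attr(dr, "mu"), tolerance = 0.01)
  expect_equal(var(dr), attr(dr, "var"), tolerance = 0.02)
  # conjugate-precision identity
  expect_equal(attr(dr, "var"), 1 / (1 / 0.04 + 1 / (2 * dt)))
})

test_that("calcium propagation is the exact linear map", {
  co <- kinetics_to_ar(0.004, 0.05, 1.5, 0.001)
  expect_equal(propagate_calcium(c(0, 0), 0, co), c(0, 0))
  expect_equal(propagate_calcium(c(0.3, 0.1), 2, co)[2], 0.3)
  # iterating from (a, 0) with no further spikes reproduces the kernel
  cv <- c(co$a, 0)
  resp <- numeric(50)
  resp[1] <- cv[1]
  for (t in 2:50) {
    cv <- propagate_calcium(cv, 0, co)
    resp[t] <- cv[1]
  }
  expect_equal(resp, kernel_response(co, 50), tolerance = 1e-12)
})

test_that("ancestor weights match direct evaluation of the stochastic factors", {
  dt <- 0.02
  theta <- slow_theta()
  # single particle gets probability one
  x_ref <- latent_state(1, 0, c(0, 0), 0.1)
  expect_equal(ancestor_weights(log(0.4), 0L, 0.0, x_ref, theta, dt), 1)
  # identical particles: uniform
  p <- ancestor_weights(rep(log(0.2), 5), rep(1L, 5), rep(0.3, 5), x_ref,
                        theta, dt)
  expect_equal(p, rep(1 / 5, 5))
  # three hand-built particles vs the direct ratio
  lw <- log(c(0.5, 0.2, 0.3))
  qp <- c(0L, 1L, 0L)
  bp <- c(0.0, 0.2, -0.4)
  p3 <- ancestor_weights(lw, qp, bp, x_ref, theta, dt)
  w_mat <- pgbar:::transition_matrix(theta, dt)
  raw <- exp(lw) * w_mat[cbind(qp + 1L, x_ref$q + 1L)] *
    dnorm(x_ref$b, bp, sqrt(theta$sigma2_b * dt))
  expect_equal(p3, raw / sum(raw), tolerance = 1e-12)
})

test_that("sweep output is calcium-consistent and pins the reference", {
  theta <- slow_theta()
  dt <- 0.01
  sim <- simulate_trace(theta, 60, dt, seed = 21)
  ref <- list(q = sim$states, s = sim$spikes, b = sim$baseline)
  set.seed(3)
  out <- pgas_sweep(sim$trace, ref, theta, n_particles = 30,
                    return_particles = TRUE)
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  # trajectory satisfies the deterministic calcium recursion at every step
  expect_equal(out$c, pgbar:::compute_calcium(out$s, co, theta$c0),
               tolerance = 1e-10)
  # conditional-SMC constraint: slot N holds the reference states throughout
  pp <- out$particles
  N <- ncol(pp$q)
  expect_equal(pp$q[, N], ref$q)
  expect_equal(pp$s[, N], ref$s)
  expect_equal(pp$b[, N], ref$b)
})

test_that("importance weights equal the proposal normalizer at every step", {
  theta <- slow_theta()
  dt <- 0.01
  sim <- simulate_trace(theta, 25, dt, seed = 22)
  ref <- list(q = sim$states, s = sim$spikes, b = sim$baseline)
  set.seed(4)
  out <- pgas_sweep(sim$trace, ref, theta, n_particles = 8,
                    return_particles = TRUE)
  pp <- out$particles
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  T_ <- nrow(pp$q)
  for (t in 2:T_) {
    for (i in seq_len(ncol(pp$q))) {
      a <- pp$anc[t, i] + 1L  # C++ indices are 0-based
      xp <- latent_state(pp$q[t - 1, a], pp$s[t - 1, a],
                         c(pp$c[t - 1, a], pp$c_prev[t - 1, a]),
                         pp$b[t - 1, a])
      tab <- build_proposal_table(xp, sim$trace$values[t], theta, co, dt,
                                  s_max = 20)
      expect_equal(pp$logw[t, i], tab$log_z, tolerance = 1e-9)
    }
  }
  # t = 1: weights are the observation density (proposal equals the prior)
  for (i in seq_len(ncol(pp$q))) {
    x1 <- latent_state(pp$q[1, i], pp$s[1, i], c(pp$c[1, i], 0), pp$b[1, i])
    expect_equal(pp$logw[1, i],
                 observation_logdensity(sim$trace$values[1], x1, theta),
                 tolerance = 1e-9)
  }
})

test_that("sweep errors on mismatched reference length", {
  theta <- slow_theta()
  sim <- simulate_trace(theta, 30, 0.01, seed = 1)
  ref <- list(q = sim$states[1:10], s = sim$spikes[1:10],
              b = sim$baseline[1:10])
  expect_error(pgas_sweep(sim$trace, ref, theta), "length")
})

test_that("PGAS single-site marginals match exhaustive enumeration", {
  # 10-step trace, s_max = 2, baseline marginalized exactly; the particle
  # Gibbs chain at fixed theta must reproduce the enumerated posterior
  dt <- 0.05
  theta <- model_parameters(r0 = 2, r1 = 10, w01 = 2, w10 = 4, a_max = 1,
                            tau_r = 0.05, tau_d = 0.5, c0 = 0.2,
                            sigma2 = 0.09, sigma2_b = 0.1)
  sim <- simulate_stimulus_trace(c(0.12, 0.31), theta, 10, dt, seed = 99,
                                 pin_baseline = FALSE)
  orc <- enumerate_posterior(sim$trace$values, dt, theta, s_max = 2L)
  set.seed(1)
  emp <- pgas_chain_marginals(sim$trace, theta, n_sweeps = 10100,
                              n_particles = 200, s_max = 2L, burn = 100L)
  # tolerances sized from Monte Carlo error at ~10^4 chained draws
  expect_lt(max(abs(emp$s_marginals - orc$s_marginals[, 1:3])), 0.025)
  expect_lt(max(abs(emp$s_mean - orc$s_mean)), 0.025)
  expect_lt(max(abs(emp$q1_prob - orc$q1_prob)), 0.04)
})

test_that("bootstrap initialization returns a consistent trajectory", {
  theta <- slow_theta()
  sim <- simulate_trace(theta, 50, 0.01, seed = 31)
  set.seed(5)
  tr <- bootstrap_trajectory(sim$trace, theta, 50)
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, 0.01)
  expect_equal(tr$c, pgbar:::compute_calcium(tr$s, co, theta$c0),
               tolerance = 1e-10)
  set.seed(5)
  tr2 <- bootstrap_trajectory(sim$trace, theta, 50)
  expect_identical(tr, tr2)
})
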