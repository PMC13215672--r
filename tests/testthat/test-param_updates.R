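# hand-built stats container for arithmetic checks
fake_stats <- function(spike_sums = c(0, 0), occupancy = c(0, 0),
                       n_trans = matrix(0L, 2, 2), rss = 0, baseline_ss = 0,
                       t_steps = 0) {
  structure(list(spike_sums = spike_sums, occupancy = occupancy,
                 n_trans = n_trans, rss = rss, baseline_ss = baseline_ss,
                 t_steps = t_steps), class = "pgbar_stats")
}

test_that("sufficient statistics are counted correctly", {
  traj <- list(q = c(0L, 0L, 1L, 1L, 0L), s = c(1L, 0L, 2L, 3L, 0L),
               c = c(1, 0.5, 2, 3, 2), b = c(0, 0.1, 0.1, 0.3, 0.2))
  trace <- fluorescence_trace(c(1, 0.7, 2.2, 3.2, 2.2), 0.01)
  st <- sufficient_stats(traj, trace)
  expect_equal(st$spike_sums, c(1, 5))
  expect_equal(st$occupancy, c(3, 2))
  expect_equal(as.numeric(st$n_trans), c(1, 1, 1, 1))  # column-major
  expect_equal(sum(st$n_trans), 4)                     # T - 1 transitions
  expect_equal(st$rss, sum(c(0, 0.1, 0.1, -0.1, 0)^2))
  expect_equal(st$baseline_ss, sum(c(0.1, 0, 0.2, -0.1)^2))
})

test_that("conjugate update arithmetic matches the closed forms", {
  pr <- gamma_prior(1, 1)
  st <- fake_stats(spike_sums = c(5, 0), occupancy = c(100, 0), t_steps = 100)
  p <- firing_rate_posterior(st, pr, dt = 0.01, regime = 0L)
  expect_equal(p$shape, 6)
  expect_equal(p$rate, 2)
  expect_equal(p$shape / p$rate, 3)  # posterior mean
  # zero spikes leave the shape unchanged
  p1 <- firing_rate_posterior(st, pr, dt = 0.01, regime = 1L)
  expect_equal(p1$shape, pr$shape)
  # the literal printed rule uses the total duration for both regimes
  p_tot <- firing_rate_posterior(st, pr, dt = 0.01, regime = 1L,
                                 exposure = "total")
  expect_equal(p_tot$rate, 1 + 0.01 * 100)

  nt <- matrix(c(500L, 0L, 3L, 0L), 2, 2)  # N00=500, N01=3
  st2 <- fake_stats(n_trans = nt, t_steps = 504)
  pw <- transition_rate_posterior(st2, gamma_prior(1, 1), dt = 0.01,
                                  from = 0L, to = 1L)
  expect_equal(pw$shape, 4)
  expect_equal(pw$rate, 6)
  # no observed transitions: shape unchanged
  pw2 <- transition_rate_posterior(st2, gamma_prior(1, 1), dt = 0.01,
                                   from = 1L, to = 0L)
  expect_equal(pw2$shape, 1)

  ps <- noise_variance_posterior(fake_stats(rss = 2, t_steps = 100),
                                 invgamma_prior(2, 1))
  expect_equal(ps$shape, 52)
  expect_equal(ps$rate, 2)
  # zero residuals leave the rate unchanged
  ps0 <- noise_variance_posterior(fake_stats(rss = 0, t_steps = 100),
                                  invgamma_prior(2, 1))
  expect_equal(ps0$rate, 1)

  pb <- baseline_variance_posterior(fake_stats(baseline_ss = 0.4,
                                               t_steps = 101),
                                    invgamma_prior(3, 0.2), dt = 0.01)
  expect_equal(pb$shape, 3 + 50)
  expect_equal(pb$rate, 0.2 + 0.4 / 0.02)
  pb0 <- baseline_variance_posterior(fake_stats(baseline_ss = 0,
                                                t_steps = 101),
                                     invgamma_prior(3, 0.2), dt = 0.01)
  expect_equal(pb0$rate, 0.2)
})

test_that("conjugate draws follow their closed-form posteriors (KS)", {
  priors <- default_priors()
  st <- fake_stats(spike_sums = c(7, 40), occupancy = c(800, 200),
                   n_trans = matrix(c(795L, 4L, 4L, 196L), 2, 2),
                   rss = 3.1, baseline_ss = 0.8, t_steps = 1000)
  dt <- 0.01
  set.seed(80)
  r_draws <- replicate(1e4, update_firing_rates(st, priors, dt))
  p0 <- firing_rate_posterior(st, priors$r0, dt, 0L)
  p1 <- firing_rate_posterior(st, priors$r1, dt, 1L)
  expect_gt(ks.test(r_draws[1, ], pgamma, shape = p0$shape,
                    rate = p0$rate)$p.value, 0.01)
  expect_gt(ks.test(r_draws[2, ], pgamma, shape = p1$shape,
                    rate = p1$rate)$p.value, 0.01)

  w_draws <- replicate(1e4, update_transition_rates(st, priors, dt))
  pw <- transition_rate_posterior(st, priors$w01, dt, 0L, 1L)
  expect_gt(ks.test(w_draws[1, ], pgamma, shape = pw$shape,
                    rate = pw$rate)$p.value, 0.01)

  s_draws <- replicate(1e4, update_noise_variance(st, priors))
  ps <- noise_variance_posterior(st, priors$sigma2)
  expect_gt(ks.test(1 / s_draws, pgamma, shape = ps$shape,
                    rate = ps$rate)$p.value, 0.01)
  expect_equal(mean(s_draws), ps$rate / (ps$shape - 1), tolerance = 0.02)

  b_draws <- replicate(1e4, update_baseline_variance(st, priors, dt))
  pb <- baseline_variance_posterior(st, priors$sigma2_b, dt)
  expect_gt(ks.test(1 / b_draws, pgamma, shape = pb$shape,
                    rate = pb$rate)$p.value, 0.01)
})

test_that("MH kernel update: degenerate proposals behave as specified", {
  theta <- slow_theta()
  sim <- simulate_trace(theta, 100, 0.01, seed = 13)
  traj <- list(q = sim$states, s = sim$spikes, c = sim$calcium,
               b = sim$baseline)
  priors <- priors_near(theta)
  # zero proposal scale: the chain is constant and every step accepts
  set.seed(6)
  up <- update_kernel_params_mh(theta, traj, sim$trace, priors,
                                c(a_max = 0, tau_r = 0, tau_d = 0, c0 = 0))
  expect_true(all(up$accepted))
  expect_equal(up$theta$a_max, theta$a_max)
  expect_equal(up$theta$tau_r, theta$tau_r)
  # huge proposals leave the support and are auto-rejected
  up2 <- update_kernel_params_mh(theta, traj, sim$trace, priors,
                                 c(a_max = 1e6, tau_r = 1e6, tau_d = 1e6,
                                   c0 = 1e6))
  expect_false(any(up2$accepted[c("tau_r", "tau_d")]))
})

test_that("MH kernel chain concentrates on the generating kinetics at low noise", {
  theta <- model_parameters(r0 = 0.1, r1 = 20, w01 = 0.5, w10 = 2,
                            a_max = 1, tau_r = 0.02, tau_d = 0.3, c0 = 0.1,
                            sigma2 = 1e-4, sigma2_b = 1e-12)
  sim <- simulate_stimulus_trace(seq(0.2, 1.4, by = 0.3), theta, 300, 0.005,
                                 seed = 14)
  traj <- list(q = sim$states, s = sim$spikes, c = sim$calcium,
               b = sim$baseline)
  priors <- priors_near(theta)
  scales <- c(a_max = 0.005, tau_r = 1e-4, tau_d = 1e-3, c0 = 5e-4)
  cur <- theta
  # start away from the truth (within the prior)
  cur$a_max <- 1.2
  cur$tau_r <- 0.025
  cur$tau_d <- 0.25
  set.seed(7)
  n_it <- 3000
  keep <- matrix(NA_real_, n_it, 3)
  for (i in seq_len(n_it)) {
    up <- update_kernel_params_mh(cur, traj, sim$trace, priors, scales)
    cur <- up$theta
    keep[i, ] <- c(cur$a_max, cur$tau_r, cur$tau_d)
  }
  est <- colMeans(keep[(n_it / 2):n_it, ])
  expect_equal(est[1], theta$a_max, tolerance = 0.05)
  expect_equal(est[2], theta$tau_r, tolerance = 0.05)
  expect_equal(est[3], theta$tau_d, tolerance = 0.05)
})
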