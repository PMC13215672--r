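test_that("kinetics_to_ar places the kernel peak at the rise time", {
  dt <- 1 / 3000
  co <- kinetics_to_ar(3.7e-3, 40e-3, a_max = 1, dt = dt)
  resp <- kernel_response(co, 1000)
  expect_equal(which.max(resp) * dt, 3.7e-3, tolerance = dt / 3.7e-3)
  # peak value reaches a_max up to grid discretization
  expect_equal(max(resp), 1, tolerance = 1e-3)
  # dense evaluation of the continuous-time form peaks exactly at tau_r
  tt <- seq(0.1, 30, by = 0.001)  # steps, fine grid
  dense <- co$a * (exp(co$g_plus * tt) - exp(co$g_minus * tt)) /
    (exp(co$g_plus) - exp(co$g_minus))
  expect_equal(tt[which.max(dense)] * dt, 3.7e-3, tolerance = 1e-3)
  expect_equal(max(dense), 1, tolerance = 1e-6)
})

test_that("reparameterization round trip is the identity on a kinetics grid", {
  dt <- 0.001
  for (tau_d in c(0.02, 0.08, 0.4)) {
    for (ratio in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
      tau_r <- ratio * tau_d
      co <- kinetics_to_ar(tau_r, tau_d, a_max = 1.7, dt = dt)
      back <- ar_to_kinetics(co, dt)
      expect_equal(back$tau_r, tau_r, tolerance = 1e-6)
      expect_equal(back$tau_d, tau_d, tolerance = 1e-6)
      expect_equal(back$a_max, 1.7, tolerance = 1e-6)
    }
  }
})

test_that("ar_to_kinetics agrees with brute-force argmax and tail slope", {
  # reference coefficients, dt = 1 step
  co <- list(gamma1 = 1.70, gamma2 = -0.712, a = 1)
  kin <- ar_to_kinetics(co, dt = 1)
  co2 <- kinetics_to_ar(kin$tau_r, kin$tau_d, kin$a_max, dt = 1)
  resp <- kernel_response(co2, 500)
  # argmax of the discrete kernel within one step of tau_r
  expect_lte(abs(which.max(resp) - kin$tau_r), 1)
  # tail regression: log-slope equals -1/tau_d within 1% past 5*tau_r
  idx <- seq(ceiling(5 * kin$tau_r), 400)
  slope <- coef(lm(log(resp[idx]) ~ idx))[2]
  expect_equal(unname(slope), -1 / kin$tau_d, tolerance = 0.01)
})

test_that("kernel closed form equals the AR(2) recursion and starts at a", {
  co <- kinetics_to_ar(0.004, 0.05, a_max = 2, dt = 0.001)
  resp <- kernel_response(co, 100)
  expect_equal(resp[1], co$a)
  rec <- numeric(100)
  rec[1] <- co$a
  rec[2] <- co$gamma1 * rec[1]
  for (t in 3:100) rec[t] <- co$gamma1 * rec[t - 1] + co$gamma2 * rec[t - 2]
  expect_equal(resp, rec, tolerance = 1e-12)
})

test_that("degenerate kinetics are rejected", {
  expect_error(kinetics_to_ar(0.05, 0.04, 1, 0.001), "tau_r < tau_d")
  expect_error(kinetics_to_ar(0.04, 0.04, 1, 0.001), "tau_r < tau_d")
  # first-order case gamma2 = 0: root at zero is a domain error
  expect_error(ar_to_kinetics(list(gamma1 = 0.9, gamma2 = 0, a = 1), 1),
               "roots")
  # complex roots
  expect_error(ar_to_kinetics(list(gamma1 = 0.2, gamma2 = -0.9, a = 1), 1),
               "roots")
})

test_that("gaussian_convolution matches the closed form, symmetry and quadrature", {
  expect_equal(gaussian_convolution(0, 0, 1, 1), 1 / sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_convolution(0, 0, 1, 1), 0.2821, tolerance = 1e-4)
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(2); v <- runif(2, 0.1, 2)
    expect_equal(gaussian_convolution(y[1], y[2], v[1], v[2]),
                 gaussian_convolution(y[2], y[1], v[2], v[1]))
    # defining integral by adaptive quadrature
    quad <- integrate(function(x) dnorm(x, y[1], sqrt(v[1])) *
                                  dnorm(x, y[2], sqrt(v[2])),
                      -Inf, Inf)$value
    expect_equal(gaussian_convolution(y[1], y[2], v[1], v[2]), quad,
                 tolerance = 1e-7)
    # normalization: integrating over y2 returns 1
    nrm <- integrate(function(y2) gaussian_convolution(y[1], y2, v[1], v[2]),
                     -Inf, Inf)$value
    expect_equal(nrm, 1, tolerance = 1e-7)
  }
  expect_equal(gaussian_convolution(1, 0, 0.5, 0.25),
               integrate(function(x) dnorm(x, 1, sqrt(0.5)) *
                                     dnorm(x, 0, sqrt(0.25)),
                         -Inf, Inf)$value, tolerance = 1e-8)
  expect_error(gaussian_convolution(0, 0, -1, 1), "positive")
})

test_that("transition density: trivial cases and Poisson term", {
  dt <- 0.01
  theta <- model_parameters(r0 = 0, r1 = 10, w01 = 2, w10 = 3, a_max = 1,
                            tau_r = 0.02, tau_d = 0.3, c0 = 0, sigma2 = 0.1,
                            sigma2_b = 0.5)
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  xp <- latent_state(0, 0, c(0, 0), 0.3)
  x <- latent_state(0, 0, propagate_calcium(c(0, 0), 0, co), 0.3)
  ld <- transition_logdensity(xp, x, theta, co, dt)
  expect_equal(ld, log(1 - 2 * dt) + dnorm(0, 0, sqrt(0.5 * dt), log = TRUE))
  # Poisson factor: s = 2 at r1*dt = 0.1
  x2 <- latent_state(1, 2, propagate_calcium(c(0, 0), 2, co), 0.3)
  ld2 <- transition_logdensity(xp, x2, theta, co, dt)
  expect_equal(exp(ld2 - log(2 * dt) -
                   dnorm(0.3, 0.3, sqrt(0.5 * dt), log = TRUE)),
               0.1^2 * exp(-0.1) / 2, tolerance = 1e-12)
  # calcium inconsistency is a contract violation
  bad <- latent_state(0, 0, c(5, 5), 0.3)
  expect_error(transition_logdensity(xp, bad, theta, co, dt), "calcium")
})

test_that("transition x observation integrates to the proposal normalizer", {
  # enumeration over (q, s) + quadrature over b equals z from the table
  set.seed(7)
  dt <- 0.02
  theta <- model_parameters(r0 = 2, r1 = 40, w01 = 3, w10 = 8, a_max = 1.2,
                            tau_r = 0.02, tau_d = 0.25, c0 = 0.1,
                            sigma2 = 0.2, sigma2_b = 0.4)
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  for (rep in 1:5) {
    xp <- random_state(theta, co)
    f <- rnorm(1, xp$c_vec[1], 0.5)
    tab <- build_proposal_table(xp, f, theta, co, dt, s_max = 20)
    z_enum <- 0
    for (q in 0:1) for (s in 0:20) {
      cv <- propagate_calcium(xp$c_vec, s, co)
      # integrand is a product of two narrow Gaussians in b; integrate over a
      # generous finite window around both centers for quadrature stability
      ctr <- c(xp$b, f - cv[1])
      hw <- 12 * sqrt(max(theta$sigma2_b * dt, theta$sigma2))
      z_enum <- z_enum + integrate(function(b) vapply(b, function(bi) {
        x <- latent_state(q, s, cv, bi)
        exp(transition_logdensity(xp, x, theta, co, dt) +
            observation_logdensity(f, x, theta))
      }, numeric(1)), min(ctr) - hw, max(ctr) + hw,
      rel.tol = 1e-10)$value
    }
    expect_equal(tab$z, z_enum, tolerance = 1e-6)
  }
})

test_that("observation density: trivial residuals and normalization", {
  theta <- slow_theta()
  x <- latent_state(0, 0, c(0.4, 0.2), 0.1)
  s2 <- theta$sigma2
  expect_equal(observation_logdensity(0.5, x, theta), -0.5 * log(2 * pi * s2))
  expect_equal(observation_logdensity(0.5 + sqrt(s2), x, theta),
               -0.5 * log(2 * pi * s2) - 0.5)
  nrm <- integrate(function(f) exp(vapply(f, observation_logdensity,
                                          numeric(1), x = x, theta = theta)),
                   -Inf, Inf)$value
  expect_equal(nrm, 1, tolerance = 1e-7)
})

test_that("initial density: equal regime mass and near-unit total mass", {
  dt <- 0.02
  theta <- slow_theta()
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  x0 <- latent_state(0, 0, c(theta$c0, 0), 0)
  expect_equal(initial_logdensity(x0, theta, co, dt),
               log(0.5) - theta$r0 * dt - 0.5 * log(2 * pi))
  x1 <- latent_state(1, 0, c(theta$c0, 0), 0)
  expect_equal(initial_logdensity(x1, theta, co, dt) -
                 initial_logdensity(x0, theta, co, dt),
               -(theta$r1 - theta$r0) * dt)  # only the Poisson rate differs
  total <- 0
  for (q in 0:1) for (s in 0:30) {
    cv <- c(theta$c0 + co$a * s, 0)
    total <- total + integrate(function(b) vapply(b, function(bi)
      exp(initial_logdensity(latent_state(q, s, cv, bi), theta, co, dt)),
      numeric(1)), -Inf, Inf)$value
  }
  expect_equal(total, 1, tolerance = 1e-8)
  expect_error(initial_logdensity(latent_state(0, 1, c(9, 0), 0), theta, co,
                                  dt), "calcium")
})

test_that("parameter and trace containers validate their invariants", {
  expect_error(model_parameters(-1, 1, 1, 1, 1, 0.01, 0.1, 0, 1, 1),
               "non-negative")
  expect_error(model_parameters(1, 1, 1, 1, -2, 0.01, 0.1, 0, 1, 1), "a_max")
  expect_error(model_parameters(1, 1, 1, 1, 1, 0.2, 0.1, 0, 1, 1), "tau")
  expect_error(fluorescence_trace(1, 0.01), "at least 2")
  expect_error(fluorescence_trace(c(1, NA), 0.01), "finite")
  expect_error(fluorescence_trace(c(1, 2), -1), "positive")
  th <- slow_theta()
  expect_error(pgbar:::validate_theta_dt(model_parameters(1, 1, 200, 1, 1, 0.01, 0.1,
                                                  0, 1, 1), 0.01), "w\\*dt")
})
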