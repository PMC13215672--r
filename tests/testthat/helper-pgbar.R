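# Shared fixture builders for the test suite. Everything is generated in code;
# no binary fixtures.

# Fast-indicator parameters used throughout the short-interval experiments:
# rise 3.7 ms, decay 40 ms, unit peak response.
fast_theta <- function(snr = 3.4, r0 = 0.1, r1 = 20, w01 = 0.5, w10 = 2,
                       c0 = 0, sigma2_b = 0.005) {
  model_parameters(r0 = r0, r1 = r1, w01 = w01, w10 = w10, a_max = 1,
                   tau_r = 0.0037, tau_d = 0.040, c0 = c0,
                   sigma2 = (1 / snr)^2, sigma2_b = sigma2_b)
}

# Coarser parameters for slow-rate tests (100 Hz sampling scale).
slow_theta <- function(snr = 10, r0 = 0.2, r1 = 20, w01 = 0.5, w10 = 2) {
  model_parameters(r0 = r0, r1 = r1, w01 = w01, w10 = w10, a_max = 1,
                   tau_r = 0.02, tau_d = 0.3, c0 = 0, sigma2 = (1 / snr)^2,
                   sigma2_b = 0.01)
}

random_state <- function(theta, coeffs, q = NULL, s = NULL) {
  if (is.null(q)) q <- sample(0:1, 1)
  if (is.null(s)) s <- rpois(1, 1)
  c_prev <- runif(2, -0.5, 2)
  latent_state(q, s, propagate_calcium(c_prev, s, coeffs), rnorm(1))
}

# Tight priors centered on a theta; used for recovery-style runs.
priors_near <- function(theta, kin_sd_frac = 0.3) {
  prior_spec(
    a_max = tnorm_prior(theta$a_max, kin_sd_frac * theta$a_max, lower = 0.01),
    c0 = tnorm_prior(0, 0.5, lower = 0),
    tau_r = tnorm_prior(theta$tau_r, kin_sd_frac * theta$tau_r,
                        lower = theta$tau_r / 10),
    tau_d = tnorm_prior(theta$tau_d, kin_sd_frac * theta$tau_d,
                        lower = theta$tau_d / 10),
    r0 = gamma_prior(1, 1), r1 = gamma_prior(2, 0.1),
    w01 = gamma_prior(1, 1), w10 = gamma_prior(2, 1),
    sigma2 = invgamma_prior(2, theta$sigma2), sigma2_b = invgamma_prior(2, 0.01))
}

# Small, fully proper priors for Geweke runs at dt = 0.05 s and short traces.
# Deliberately noisy (sigma2 prior mean ~0.3): the successive-conditional
# chain's slowest mode is the baseline level, whose mixing rate scales with
# the prior-to-likelihood precision ratio of b1 — short, noisy traces keep
# the correlation time in the tens of rounds so 10^4 rounds give honest power.
geweke_priors <- function() {
  prior_spec(
    a_max = tnorm_prior(1, 0.2, lower = 0.3),
    c0 = tnorm_prior(0.2, 0.2, lower = 0),
    tau_r = tnorm_prior(0.1, 0.02, lower = 0.02),
    tau_d = tnorm_prior(0.8, 0.15, lower = 0.2),
    r0 = gamma_prior(4, 2), r1 = gamma_prior(4, 0.5),
    w01 = gamma_prior(4, 8), w10 = gamma_prior(4, 4),
    sigma2 = invgamma_prior(8, 2), sigma2_b = invgamma_prior(8, 2))
}
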