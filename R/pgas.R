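#' Optimal proposal table over firing state and spike count
#'
#' Builds the discrete part of the optimal proposal
#' `P(q_t, s_t | X_{t-1}, F_t)`: for each regime `q'` and spike count
#' `s' = 0..s_max` the entry is proportional to
#' `W[q_prev, q'] * Poisson(s'; r_q' dt) * I(b_prev, F_t - c_t(s'), sigma2_b*dt, sigma2)`
#' where `c_t(s')` is the deterministically propagated calcium and `I` is the
#' Gaussian convolution that marginalizes the baseline analytically. Computed
#' in log space with max-subtraction; the pre-normalization sum `z` is the
#' importance weight of the particle.
#'
#' @param x_prev a `pgbar_state` at time `t-1`.
#' @param f fluorescence observation at time `t`.
#' @param theta a `pgbar_theta` object.
#' @param coeffs a `pgbar_kernel` object.
#' @param dt sampling period (s).
#' @param s_max spike-count cutoff per step (support is `0..s_max`).
#' @return List with `table` (2 x (s_max+1) matrix of normalized
#'   probabilities, rows = regimes 0/1), `log_z`, `z` and `c_pred` (calcium
#'   propagated without new spikes).
#' @export
build_proposal_table <- function(x_prev, f, theta, coeffs, dt, s_max = 20L) {
  validate_theta_dt(theta, dt)
  c_pred <- coeffs$gamma1 * x_prev$c_vec[1] + coeffs$gamma2 * x_prev$c_vec[2]
  v <- theta$sigma2 + theta$sigma2_b * dt
  s_vals <- 0:s_max
  lW <- log(transition_matrix(theta, dt))
  lent <- matrix(-Inf, 2, s_max + 1L)
  for (qp in 0:1) {
    r <- if (qp == 1L) theta$r1 else theta$r0
    diff <- x_prev$b - (f - c_pred - coeffs$a * s_vals)
    lent[qp + 1L, ] <- lW[x_prev$q + 1L, qp + 1L] +
      stats::dpois(s_vals, r * dt, log = TRUE) - 0.5 * diff^2 / v
  }
  mx <- max(lent)
  if (!is.finite(mx))
    stop("all proposal-table entries underflowed")
  log_z <- mx + log(sum(exp(lent - mx))) - 0.5 * log(2 * pi * v)
  tab <- exp(lent - mx)
  tab <- tab / sum(tab)
  dimnames(tab) <- list(q = c("0", "1"), s = as.character(s_vals))
  list(table = tab, log_z = log_z, z = exp(log_z), c_pred = c_pred)
}

#' Draw the baseline from its full conditional
#'
#' Gaussian with mean
#' `(b_prev*sigma2 + (f - c_t)*sigma2_b*dt) / (sigma2 + sigma2_b*dt)` and
#' variance `(1/sigma2 + 1/(sigma2_b*dt))^-1`.
#'
#' @param x_prev a `pgbar_state` at time `t-1`.
#' @param c_t calcium level at time `t`.
#' @param f fluorescence observation at time `t`.
#' @param theta a `pgbar_theta` object.
#' @param dt sampling period (s).
#' @param n number of draws.
#' @return Numeric draws of length `n`; attributes `mu` and `var` carry the
#'   conditional moments.
#' @export
sample_baseline <- function(x_prev, c_t, f, theta, dt, n = 1) {
  sb <- theta$sigma2_b * dt
  if (theta$sigma2 <= 0 || sb <= 0) stop("sigma2 and sigma2_b*dt must be > 0")
  mu <- (x_prev$b * theta$sigma2 + (f - c_t) * sb) / (theta$sigma2 + sb)
  v <- 1 / (1 / theta$sigma2 + 1 / sb)
  structure(stats::rnorm(n, mu, sqrt(v)), mu = mu, var = v)
}

#' Deterministic calcium propagation
#'
#' `C_t = M C_{t-1} + a*(s, 0)` with `M = [[gamma1, gamma2], [1, 0]]`.
#'
#' @param c_vec_prev calcium pair `(c_{t-1}, c_{t-2})`.
#' @param s spike count at time `t`.
#' @param coeffs a `pgbar_kernel` object.
#' @return Calcium pair `(c_t, c_{t-1})`.
#' @export
propagate_calcium <- function(c_vec_prev, s, coeffs) {
  c(coeffs$gamma1 * c_vec_prev[1] + coeffs$gamma2 * c_vec_prev[2] +
      coeffs$a * s,
    c_vec_prev[1])
}

#' Ancestor-sampling junction factors for the reference particle
#'
#' Probability over ancestors `i` proportional to
#' `w_{t-1}^(i) * W[q_i, q_ref] * N(b_ref; b_i, sigma2_b*dt)` — the stochastic
#' factors of the latent transition density to the reference state at the
#' reconnection point. The deterministic-calcium delta is not a density
#' factor (it would almost surely vanish for every ancestor); instead the
#' connected history's calcium is re-propagated forward from the chosen
#' ancestor. Because that re-propagation changes the calcium entering every
#' later observation, the sweep itself multiplies these junction factors by
#' the exact future-observation likelihood ratio (a quadratic form in the
#' ancestor's calcium pair; see the methods vignette) — without it the
#' sampler is measurably biased. This helper exposes the junction factors
#' alone.
#'
#' @param log_weights log importance weights at time `t-1` (length `N`).
#' @param q_prev,b_prev regime and baseline of each particle at `t-1`.
#' @param x_ref_t the reference `pgbar_state` at time `t`.
#' @param theta a `pgbar_theta` object.
#' @param dt sampling period (s).
#' @return Probability vector over the `N` particles. If every score
#'   underflows, falls back to the normalized weights with a warning.
#' @export
ancestor_weights <- function(log_weights, q_prev, b_prev, x_ref_t, theta, dt) {
  lW <- log(transition_matrix(theta, dt))
  sc <- log_weights + lW[cbind(q_prev + 1L, x_ref_t$q + 1L)] +
    stats::dnorm(x_ref_t$b, b_prev, sqrt(theta$sigma2_b * dt), log = TRUE)
  mx <- max(sc)
  if (!is.finite(mx)) {
    warning("all ancestor scores underflowed; falling back to plain weights")
    sc <- log_weights
    mx <- max(sc)
  }
  p <- exp(sc - mx)
  p / sum(p)
}

#' One PGAS sweep
#'
#' Runs the conditional sequential Monte Carlo pass with ancestor sampling:
#' initialization from the initial-state distribution (reference pinned in
#' slot `N`), then per step multinomial resampling of `N-1` ancestors,
#' ancestor sampling for the reference slot, proposal draws of `(q, s)` from
#' the optimal-proposal table, deterministic calcium propagation, a baseline
#' draw from its full conditional and weight assignment
#' `w = Z(X_{t-1}, F_t)`; finally one trajectory is drawn proportionally to
#' the terminal weights.
#'
#' @param trace a `pgbar_trace` object.
#' @param x_ref reference trajectory: list with integer vectors `q`, `s` and
#'   numeric `b`, each of length `T` (calcium is re-derived from `s` under the
#'   current kinetics).
#' @param theta a `pgbar_theta` object.
#' @param n_particles number of particles `N >= 2`.
#' @param s_max spike-count cutoff per step.
#' @param single_state non-bursting variant (regime pinned at 0).
#' @param return_particles also return the full particle system (testing).
#' @param mutation internal test fixture: 0 = none, 1 = squared log-weights,
#'   2 = negated log-weights. Deliberately breaks the sampler for the Geweke
#'   mutation test; never use for inference.
#' @param ancestor_sampling draw the reference slot's ancestor by ancestor
#'   sampling (default). `FALSE` keeps the reference lineage intact (plain
#'   particle Gibbs; slower mixing, used as a diagnostic baseline).
#' @return List with the new trajectory `q`, `s`, `c`, `b` and the count of
#'   ancestor-sampling fallbacks; `particles` when requested.
#' @export
pgas_sweep <- function(trace, x_ref, theta, n_particles = 100L, s_max = 20L,
                      single_state = FALSE, return_particles = FALSE,
                      mutation = 0L, ancestor_sampling = TRUE) {
  stopifnot(inherits(trace, "pgbar_trace"))
  T_ <- length(trace$values)
  if (length(x_ref$q) != T_ || length(x_ref$s) != T_ || length(x_ref$b) != T_)
    stop("reference trajectory length does not match the trace")
  validate_theta_dt(theta, trace$dt)
  coeffs <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, trace$dt)
  cpp_pgas_sweep(trace$values, trace$dt, as.integer(x_ref$q),
                 as.integer(x_ref$s), as.numeric(x_ref$b),
                 theta$r0, theta$r1, theta$w01, theta$w10,
                 coeffs$gamma1, coeffs$gamma2, coeffs$a, theta$c0,
                 theta$sigma2, theta$sigma2_b, as.integer(n_particles),
                 as.integer(s_max), single_state, as.integer(mutation),
                 return_particles, isTRUE(ancestor_sampling))
}

#' Bootstrap particle filter trajectory draw
#'
#' Plain bootstrap filter (propose from the prior transition, weight by the
#' observation density, multinomial resampling each step) returning one
#' trajectory drawn proportionally to the terminal weights. Used to
#' initialize the Gibbs sampler with a calcium-consistent reference.
#'
#' @inheritParams pgas_sweep
#' @param max_retries on full weight degeneracy, retry with observation noise
#'   inflated 10-fold, up to this many times.
#' @return List with `q`, `s`, `c`, `b`.
#' @export
bootstrap_trajectory <- function(trace, theta, n_particles = 100L,
                                 single_state = FALSE, max_retries = 3L) {
  stopifnot(inherits(trace, "pgbar_trace"))
  validate_theta_dt(theta, trace$dt)
  coeffs <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, trace$dt)
  sigma2 <- theta$sigma2
  for (k in 0:max_retries) {
    res <- cpp_bootstrap_filter(trace$values, trace$dt, theta$r0, theta$r1,
                                theta$w01, theta$w10, coeffs$gamma1,
                                coeffs$gamma2, coeffs$a, theta$c0, sigma2,
                                theta$sigma2_b, as.integer(n_particles),
                                single_state)
    if (isTRUE(res$ok)) return(res[c("q", "s", "c", "b")])
    sigma2 <- sigma2 * 10
  }
  stop("bootstrap filter degenerate even with inflated noise (failed at t = ",
       res$t_fail, ")")
}
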