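#' Sufficient statistics of a latent trajectory
#'
#' Collects everything the parameter updates need: per-regime spike sums and
#' occupancies, regime transition counts, the observation residual sum of
#' squares and the baseline increment sum of squares.
#'
#' @param trajectory list with `q`, `s`, `c`, `b` (lengths `T`).
#' @param trace a `pgbar_trace` object.
#' @return List of class `pgbar_stats`: `spike_sums` (length 2, regimes 0/1),
#'   `occupancy` (steps per regime), `n_trans` (2x2 matrix of transition
#'   counts), `rss`, `baseline_ss`, `t_steps`.
#' @export
sufficient_stats <- function(trajectory, trace) {
  q <- trajectory$q
  s <- trajectory$s
  T_ <- length(q)
  if (length(trace$values) != T_) stop("trajectory/trace length mismatch")
  spike_sums <- c(sum(s[q == 0L]), sum(s[q == 1L]))
  occupancy <- c(sum(q == 0L), sum(q == 1L))
  n_trans <- matrix(0L, 2, 2, dimnames = list(from = c("0", "1"),
                                              to = c("0", "1")))
  if (T_ > 1) {
    fr <- q[-T_] + 1L
    to <- q[-1L] + 1L
    for (i in 1:2) for (j in 1:2)
      n_trans[i, j] <- sum(fr == i & to == j)
  }
  structure(list(spike_sums = spike_sums, occupancy = occupancy,
                 n_trans = n_trans,
                 rss = sum((trace$values - trajectory$c - trajectory$b)^2),
                 baseline_ss = sum(diff(trajectory$b)^2),
                 t_steps = T_),
            class = "pgbar_stats")
}

#' Conjugate posterior hyperparameters
#'
#' Closed-form full-conditional hyperparameters behind the conjugate draws;
#' exposed so the update arithmetic is testable without Monte Carlo.
#'
#' @param stats a `pgbar_stats` object.
#' @param prior the relevant `pgbar_prior`.
#' @param dt sampling period (s).
#' @param regime firing regime (0 or 1).
#' @param exposure `"occupancy"` uses the per-regime exposure `dt * T_q`
#'   implied by the Poisson likelihood; `"total"` uses the literal total
#'   duration `dt * T` for both regimes.
#' @return Named list `shape`, `rate`.
#' @name conjugate-posteriors
NULL

#' @rdname conjugate-posteriors
#' @export
firing_rate_posterior <- function(stats, prior, dt, regime,
                                  exposure = c("occupancy", "total")) {
  exposure <- match.arg(exposure)
  expo <- if (exposure == "occupancy") stats$occupancy[regime + 1L]
          else stats$t_steps
  list(shape = prior$shape + stats$spike_sums[regime + 1L],
       rate = prior$rate + dt * expo)
}

#' @rdname conjugate-posteriors
#' @param from,to regimes of the switching transition (`from != to`).
#' @export
transition_rate_posterior <- function(stats, prior, dt, from, to) {
  if (from == to) stop("switching updates need from != to")
  list(shape = prior$shape + stats$n_trans[from + 1L, to + 1L],
       rate = prior$rate + dt * stats$n_trans[from + 1L, from + 1L])
}

#' @rdname conjugate-posteriors
#' @export
noise_variance_posterior <- function(stats, prior) {
  list(shape = prior$shape + stats$t_steps / 2,
       rate = prior$rate + stats$rss / 2)
}

#' @rdname conjugate-posteriors
#' @export
baseline_variance_posterior <- function(stats, prior, dt) {
  list(shape = prior$shape + (stats$t_steps - 1) / 2,
       rate = prior$rate + stats$baseline_ss / (2 * dt))
}

#' Gibbs draws of the firing rates
#'
#' `r_q ~ Gamma(alpha + sum of spikes in regime q, beta + dt * T_q)`.
#'
#' @param stats a `pgbar_stats` object.
#' @param priors a `pgbar_priors` object.
#' @param dt sampling period (s).
#' @param exposure see [firing_rate_posterior()].
#' @return Named vector `c(r0, r1)`.
#' @export
update_firing_rates <- function(stats, priors, dt,
                                exposure = c("occupancy", "total")) {
  exposure <- match.arg(exposure)
  p0 <- firing_rate_posterior(stats, priors$r0, dt, 0L, exposure)
  p1 <- firing_rate_posterior(stats, priors$r1, dt, 1L, exposure)
  c(r0 = stats::rgamma(1, shape = p0$shape, rate = p0$rate),
    r1 = stats::rgamma(1, shape = p1$shape, rate = p1$rate))
}

#' Gibbs draws of the regime switching rates
#'
#' `w_{q->q'} ~ Gamma(alpha + N_qq', beta + dt * N_qq)` under the
#' slow-switching approximation. Draws violating `w*dt < 1` are redrawn with a
#' warning; after `max_attempts` the draw is capped just below `1/dt`.
#'
#' @inheritParams update_firing_rates
#' @param max_attempts redraw budget per rate.
#' @return Named vector `c(w01, w10)`.
#' @export
update_transition_rates <- function(stats, priors, dt, max_attempts = 100L) {
  draw <- function(prior, from, to) {
    p <- transition_rate_posterior(stats, prior, dt, from, to)
    for (i in seq_len(max_attempts)) {
      w <- stats::rgamma(1, shape = p$shape, rate = p$rate)
      if (w * dt < 1) return(w)
      if (i == 1L) warning("switching-rate draw with w*dt >= 1; redrawing")
    }
    (1 - 1e-9) / dt
  }
  c(w01 = draw(priors$w01, 0L, 1L), w10 = draw(priors$w10, 1L, 0L))
}

#' Gibbs draw of the observation-noise variance
#'
#' `sigma2 ~ InvGamma(alpha + T/2, beta + RSS/2)`.
#'
#' @inheritParams update_firing_rates
#' @return Scalar draw.
#' @export
update_noise_variance <- function(stats, priors) {
  p <- noise_variance_posterior(stats, priors$sigma2)
  1 / stats::rgamma(1, shape = p$shape, rate = p$rate)
}

#' Gibbs draw of the baseline variance rate
#'
#' Conjugate extension implied by the Gaussian random-walk baseline:
#' `sigma2_b ~ InvGamma(alpha + (T-1)/2, beta + sum (b_t - b_{t-1})^2 / (2 dt))`.
#'
#' @inheritParams update_firing_rates
#' @return Scalar draw.
#' @export
update_baseline_variance <- function(stats, priors, dt) {
  p <- baseline_variance_posterior(stats, priors$sigma2_b, dt)
  1 / stats::rgamma(1, shape = p$shape, rate = p$rate)
}

# Gaussian observation log-likelihood of the whole trace for a candidate
# (a_max, tau_r, tau_d, c0), with calcium recomputed from the fixed spikes.
.kernel_loglik <- function(values, s, b, a_max, tau_r, tau_d, c0, sigma2, dt) {
  coeffs <- tryCatch(kinetics_to_ar(tau_r, tau_d, a_max, dt),
                     error = function(e) NULL)
  if (is.null(coeffs)) return(list(ll = -Inf, c = NULL))
  cc <- compute_calcium(s, coeffs, c0)
  list(ll = sum(stats::dnorm(values, cc + b, sqrt(sigma2), log = TRUE)),
       c = cc)
}

#' Metropolis-Hastings update of the kernel parameters and c0
#'
#' One random-walk MH step per parameter (`a_max`, `tau_r`, `tau_d`, `c0`),
#' accepting on prior times likelihood where the likelihood is the Gaussian
#' observation density of the full trace with calcium recomputed from the
#' fixed spike sequence under the proposed kinetics. Proposals outside the
#' prior support or violating `tau_r < tau_d` are auto-rejected.
#'
#' @param theta current `pgbar_theta`.
#' @param trajectory current latent trajectory (`q`, `s`, `c`, `b`).
#' @param trace a `pgbar_trace` object.
#' @param priors a `pgbar_priors` object.
#' @param proposal_scales named numeric vector of random-walk standard
#'   deviations for `a_max`, `tau_r`, `tau_d`, `c0`.
#' @return List with updated `theta` (calcium-consistent `calcium` vector
#'   attached as `$calcium`) and logical `accepted` per parameter.
#' @export
update_kernel_params_mh <- function(theta, trajectory, trace, priors,
                                    proposal_scales) {
  par_names <- c("a_max", "tau_r", "tau_d", "c0")
  cur <- list(a_max = theta$a_max, tau_r = theta$tau_r, tau_d = theta$tau_d,
              c0 = theta$c0)
  ll_cur <- .kernel_loglik(trace$values, trajectory$s, trajectory$b,
                           cur$a_max, cur$tau_r, cur$tau_d, cur$c0,
                           theta$sigma2, trace$dt)
  accepted <- stats::setNames(logical(4), par_names)
  for (nm in par_names) {
    cand <- cur
    cand[[nm]] <- cur[[nm]] + stats::rnorm(1, 0, proposal_scales[[nm]])
    pr <- priors[[nm]]
    in_support <- cand[[nm]] >= pr$lower && cand[[nm]] <= pr$upper &&
      cand$tau_r < cand$tau_d && cand$a_max > 0
    if (!in_support) next
    ll_cand <- .kernel_loglik(trace$values, trajectory$s, trajectory$b,
                              cand$a_max, cand$tau_r, cand$tau_d, cand$c0,
                              theta$sigma2, trace$dt)
    log_alpha <- (dprior(pr, cand[[nm]], log = TRUE) + ll_cand$ll) -
                 (dprior(pr, cur[[nm]], log = TRUE) + ll_cur$ll)
    if (is.na(log_alpha)) next
    if (log_alpha >= 0 || log(stats::runif(1)) < log_alpha) {
      cur <- cand
      ll_cur <- ll_cand
      accepted[nm] <- TRUE
    }
  }
  theta$a_max <- cur$a_max
  theta$tau_r <- cur$tau_r
  theta$tau_d <- cur$tau_d
  theta$c0 <- cur$c0
  list(theta = theta, calcium = ll_cur$c, accepted = accepted)
}
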