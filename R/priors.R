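#' Prior distribution specifications
#'
#' Families are fixed per parameter: truncated-normal priors for the kernel
#' parameters `a_max`, `c0`, `tau_r`, `tau_d`; gamma priors for the rate
#' parameters `r0`, `r1`, `w01`, `w10`; inverse-gamma priors for the variance
#' parameters `sigma2` and `sigma2_b`.
#'
#' @param mean,sd location and scale of a truncated normal.
#' @param lower,upper truncation bounds.
#' @name prior-families
NULL

#' @rdname prior-families
#' @export
tnorm_prior <- function(mean, sd, lower = 0, upper = Inf) {
  if (sd <= 0) stop("sd must be positive")
  if (lower >= upper) stop("need lower < upper")
  structure(list(family = "truncated-normal", mean = mean, sd = sd,
                 lower = lower, upper = upper), class = "pgbar_prior")
}

#' @rdname prior-families
#' @param shape,rate gamma / inverse-gamma hyperparameters, both `> 0`.
#' @export
gamma_prior <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  structure(list(family = "gamma", shape = shape, rate = rate),
            class = "pgbar_prior")
}

#' @rdname prior-families
#' @export
invgamma_prior <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  structure(list(family = "inverse-gamma", shape = shape, rate = rate),
            class = "pgbar_prior")
}

.prior_families <- c(
  a_max = "truncated-normal", c0 = "truncated-normal",
  tau_r = "truncated-normal", tau_d = "truncated-normal",
  r0 = "gamma", r1 = "gamma", w01 = "gamma", w10 = "gamma",
  sigma2 = "inverse-gamma", sigma2_b = "inverse-gamma")

#' Assemble a full prior specification
#'
#' One prior per model parameter, with the family fixed by the parameter (see
#' [prior-families]). Validates families and requires the prior mean of
#' `tau_r` to sit below the prior mean of `tau_d`.
#'
#' @param a_max,c0,tau_r,tau_d truncated-normal priors.
#' @param r0,r1,w01,w10 gamma priors.
#' @param sigma2,sigma2_b inverse-gamma priors.
#' @return An object of class `pgbar_priors` (named list of `pgbar_prior`).
#' @export
prior_spec <- function(a_max, c0, tau_r, tau_d, r0, r1, w01, w10,
                       sigma2, sigma2_b) {
  pr <- list(a_max = a_max, c0 = c0, tau_r = tau_r, tau_d = tau_d,
             r0 = r0, r1 = r1, w01 = w01, w10 = w10,
             sigma2 = sigma2, sigma2_b = sigma2_b)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (!inherits(p, "pgbar_prior"))
      stop("prior for '", nm, "' must be built with *_prior()")
    if (p$family != .prior_families[[nm]])
      stop("parameter '", nm, "' requires a ", .prior_families[[nm]],
           " prior, got ", p$family)
  }
  if (prior_mean(pr$tau_r) >= prior_mean(pr$tau_d))
    stop("tau_r prior mean must be below tau_d prior mean")
  structure(pr, class = "pgbar_priors")
}

#' Default priors
#'
#' Weakly informative defaults for a fast, approximately linear calcium
#' indicator imaged at high frame rate: unitary response near 1 dF/F, rise
#' time a few ms, decay a few tens of ms, baseline firing below a few Hz and
#' burst firing in the tens of Hz. All hyperparameters are plain config values
#' that users should adapt to their indicator (see the shipped
#' `default_config.json`).
#'
#' @return A `pgbar_priors` object.
#' @export
default_priors <- function() {
  prior_spec(
    a_max = tnorm_prior(1.0, 0.5, lower = 0.01),
    c0 = tnorm_prior(0, 0.5, lower = 0),
    tau_r = tnorm_prior(0.004, 0.002, lower = 2e-4),
    tau_d = tnorm_prior(0.040, 0.020, lower = 2e-3),
    r0 = gamma_prior(1, 1),
    r1 = gamma_prior(2, 0.1),
    w01 = gamma_prior(1, 1),
    w10 = gamma_prior(2, 1),
    sigma2 = invgamma_prior(2, 0.1),
    sigma2_b = invgamma_prior(2, 0.01))
}

#' Prior density, draws and moments
#'
#' @param prior a single `pgbar_prior`.
#' @param x evaluation points.
#' @param log return log-density.
#' @return `dprior`: (log-)density values; `rprior`: `n` draws;
#'   `prior_mean`/`prior_sd`: scalars.
#' @export
dprior <- function(prior, x, log = FALSE) {
  lv <- switch(prior$family,
    "truncated-normal" = {
      lz <- base::log(stats::pnorm(prior$upper, prior$mean, prior$sd) -
                      stats::pnorm(prior$lower, prior$mean, prior$sd))
      ifelse(x >= prior$lower & x <= prior$upper,
             stats::dnorm(x, prior$mean, prior$sd, log = TRUE) - lz, -Inf)
    },
    "gamma" = stats::dgamma(x, shape = prior$shape, rate = prior$rate,
                            log = TRUE),
    "inverse-gamma" = ifelse(x > 0,
      prior$shape * base::log(prior$rate) - lgamma(prior$shape) -
        (prior$shape + 1) * base::log(x) - prior$rate / x, -Inf))
  if (log) lv else exp(lv)
}

#' @rdname dprior
#' @param n number of draws.
#' @export
rprior <- function(prior, n = 1) {
  switch(prior$family,
    "truncated-normal" = {
      plo <- stats::pnorm(prior$lower, prior$mean, prior$sd)
      phi <- stats::pnorm(prior$upper, prior$mean, prior$sd)
      stats::qnorm(plo + stats::runif(n) * (phi - plo), prior$mean, prior$sd)
    },
    "gamma" = stats::rgamma(n, shape = prior$shape, rate = prior$rate),
    "inverse-gamma" = 1 / stats::rgamma(n, shape = prior$shape,
                                        rate = prior$rate))
}

#' @rdname dprior
#' @export
prior_mean <- function(prior) {
  switch(prior$family,
    "truncated-normal" = {
      a <- (prior$lower - prior$mean) / prior$sd
      b <- (prior$upper - prior$mean) / prior$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      prior$mean + prior$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    },
    "gamma" = prior$shape / prior$rate,
    "inverse-gamma" = if (prior$shape > 1) prior$rate / (prior$shape - 1)
                      else prior$rate / (prior$shape + 1))  # mode fallback
}

#' @rdname dprior
#' @export
prior_sd <- function(prior) {
  switch(prior$family,
    "truncated-normal" = {
      a <- (prior$lower - prior$mean) / prior$sd
      b <- (prior$upper - prior$mean) / prior$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      da <- stats::dnorm(a); db <- stats::dnorm(b)
      ta <- if (is.finite(a)) a * da else 0
      tb <- if (is.finite(b)) b * db else 0
      v <- 1 + (ta - tb) / z - ((da - db) / z)^2
      prior$sd * sqrt(max(v, 0))
    },
    "gamma" = sqrt(prior$shape) / prior$rate,
    "inverse-gamma" = if (prior$shape > 2)
      prior$rate / ((prior$shape - 1) * sqrt(prior$shape - 2))
    else prior$rate / prior$shape)  # loose scale fallback
}

# Draw a full theta from the priors. Switching-rate draws are rejected until
# w*dt < 1 so that the prior and the conditional updates share one support.
draw_theta_from_priors <- function(priors, dt, max_tries = 1000L) {
  draw_w <- function(p) {
    for (i in seq_len(max_tries)) {
      w <- rprior(p)
      if (w * dt < 1) return(w)
    }
    stop("could not draw a switching rate with w*dt < 1; check priors vs dt")
  }
  repeat {
    tau_r <- rprior(priors$tau_r)
    tau_d <- rprior(priors$tau_d)
    if (tau_r < tau_d) break
  }
  model_parameters(
    r0 = rprior(priors$r0), r1 = rprior(priors$r1),
    w01 = draw_w(priors$w01), w10 = draw_w(priors$w10),
    a_max = rprior(priors$a_max), tau_r = tau_r, tau_d = tau_d,
    c0 = rprior(priors$c0), sigma2 = rprior(priors$sigma2),
    sigma2_b = rprior(priors$sigma2_b))
}

# Deterministic start at prior means (tau ordering enforced by prior_spec).
theta_from_prior_means <- function(priors) {
  model_parameters(
    r0 = prior_mean(priors$r0), r1 = prior_mean(priors$r1),
    w01 = prior_mean(priors$w01), w10 = prior_mean(priors$w10),
    a_max = prior_mean(priors$a_max), tau_r = prior_mean(priors$tau_r),
    tau_d = prior_mean(priors$tau_d), c0 = prior_mean(priors$c0),
    sigma2 = prior_mean(priors$sigma2), sigma2_b = prior_mean(priors$sigma2_b))
}

#' Calibrated priors for a fast indicator at high frame rate
#'
#' Prior set used by the short-inter-spike-interval simulation experiments:
#' kinetics and unitary amplitude centered on a single-action-potential
#' characterization of a fast indicator (rise 3.7 ms, decay 40 ms, unit
#' dF/F peak), mirroring the workflow where single-stimulation trials fix
#' the kernel priors before analyzing spike trains. Compared with
#' [default_priors()] the kernel priors are tighter; rate and variance
#' priors are unchanged.
#'
#' @return A `pgbar_priors` object.
#' @export
fast_indicator_priors <- function() {
  prior_spec(
    a_max = tnorm_prior(1, 0.15, lower = 0.2),
    c0 = tnorm_prior(0, 0.1, lower = 0),
    tau_r = tnorm_prior(0.0037, 0.001, lower = 5e-4),
    tau_d = tnorm_prior(0.040, 0.010, lower = 5e-3),
    r0 = gamma_prior(1, 1),
    r1 = gamma_prior(2, 0.1),
    w01 = gamma_prior(1, 1),
    w10 = gamma_prior(2, 1),
    sigma2 = invgamma_prior(2, 0.1),
    sigma2_b = invgamma_prior(2, 0.01))
}
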