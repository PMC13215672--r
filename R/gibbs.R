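#' Sampler configuration
#'
#' @param n_iterations total Gibbs iterations.
#' @param burn_in iterations discarded before retention (default 20% of
#'   `n_iterations`).
#' @param thinning retention stride, `>= 1`.
#' @param n_particles PGAS particle count `N >= 2`.
#' @param s_max per-step spike-count cutoff of the optimal proposal.
#' @param seed integer seed recorded and applied by [run_sampler()].
#' @param bursting `FALSE` runs the non-bursting variant (single global
#'   Poisson rate, regime pinned at 0, switching rates not updated).
#' @param update_sigma2_b update the baseline variance rate by its conjugate
#'   draw (`FALSE` holds it fixed).
#' @param exposure firing-rate exposure convention, see
#'   [firing_rate_posterior()].
#' @param deterministic_start initialize theta at the prior means instead of a
#'   prior draw.
#' @param adapt adapt MH proposal scales during burn-in (Robbins-Monro,
#'   frozen afterwards).
#' @param mh_scale_frac initial MH proposal scale as a fraction of each
#'   prior's standard deviation.
#' @param log_file optional path for a JSON-lines run log.
#' @return An object of class `pgbar_config`.
#' @export
sampler_config <- function(n_iterations = 1500L, burn_in = NULL, thinning = 1L,
                           n_particles = 100L, s_max = 20L, seed = 1L,
                           bursting = TRUE, update_sigma2_b = TRUE,
                           exposure = c("occupancy", "total"),
                           deterministic_start = FALSE, adapt = TRUE,
                           mh_scale_frac = 0.1, log_file = NULL) {
  if (is.null(burn_in)) burn_in <- as.integer(floor(n_iterations * 0.2))
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (thinning < 1) stop("thinning must be >= 1")
  if (n_particles < 2) stop("n_particles must be >= 2")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_particles = as.integer(n_particles),
                 s_max = as.integer(s_max), seed = as.integer(seed),
                 bursting = isTRUE(bursting),
                 update_sigma2_b = isTRUE(update_sigma2_b),
                 exposure = match.arg(exposure),
                 deterministic_start = isTRUE(deterministic_start),
                 adapt = isTRUE(adapt), mh_scale_frac = mh_scale_frac,
                 log_file = log_file),
            class = "pgbar_config")
}

#' Initialize the Gibbs sampler
#'
#' Draws `theta` from the priors (or sets it to the prior means in
#' deterministic-start mode) and produces an initial reference trajectory from
#' a plain bootstrap particle filter at that `theta`, which guarantees a
#' calcium-consistent latent state.
#'
#' @param trace a `pgbar_trace` object.
#' @param priors a `pgbar_priors` object.
#' @param config a `pgbar_config` object.
#' @return List with `theta` and `x_ref` (`q`, `s`, `c`, `b`).
#' @export
initialize_sampler <- function(trace, priors, config) {
  theta <- if (config$deterministic_start) theta_from_prior_means(priors)
           else draw_theta_from_priors(priors, trace$dt)
  if (!config$bursting) theta$r1 <- theta$r0
  x_ref <- bootstrap_trajectory(trace, theta, config$n_particles,
                                single_state = !config$bursting)
  list(theta = theta, x_ref = x_ref)
}

# One full Gibbs iteration: PGAS trajectory draw, conjugate rate/variance
# draws, MH kernel-parameter block. Returns the updated pair plus diagnostics.
gibbs_step <- function(trace, priors, config, theta, x_ref, mh_scales,
                       mutation = 0L) {
  traj <- pgas_sweep(trace, x_ref, theta, config$n_particles, config$s_max,
                     single_state = !config$bursting, mutation = mutation)
  stats <- sufficient_stats(traj, trace)

  if (config$bursting) {
    rr <- update_firing_rates(stats, priors, trace$dt, config$exposure)
    theta$r0 <- rr[["r0"]]
    theta$r1 <- rr[["r1"]]
    ww <- update_transition_rates(stats, priors, trace$dt)
    theta$w01 <- ww[["w01"]]
    theta$w10 <- ww[["w10"]]
  } else {
    # single global rate informed by all spikes over the whole duration
    p <- list(shape = priors$r0$shape + sum(stats$spike_sums),
              rate = priors$r0$rate + trace$dt * stats$t_steps)
    r <- stats::rgamma(1, shape = p$shape, rate = p$rate)
    theta$r0 <- r
    theta$r1 <- r
  }
  theta$sigma2 <- update_noise_variance(stats, priors)
  if (config$update_sigma2_b)
    theta$sigma2_b <- update_baseline_variance(stats, priors, trace$dt)

  mh <- update_kernel_params_mh(theta, traj, trace, priors, mh_scales)
  theta <- mh$theta
  traj$c <- mh$calcium  # keep stored calcium consistent with new kinetics

  list(theta = theta, x_ref = traj, accepted = mh$accepted,
       n_fallbacks = traj$n_ancestor_fallbacks)
}

#' Run the full Gibbs sampler
#'
#' Alternates PGAS trajectory draws with parameter updates for
#' `n_iterations`, applying burn-in and thinning. Fully reproducible under
#' the configured seed.
#'
#' @param trace a `pgbar_trace` object.
#' @param priors a `pgbar_priors` object (default [default_priors()]).
#' @param config a `pgbar_config` object (default [sampler_config()]).
#' @return An object of class `pgbar_samples`: list with `theta` (data.frame,
#'   one row per retained draw), `spikes`, `states`, `baseline` (matrices,
#'   draws x T), `acceptance` (mean MH acceptance per parameter),
#'   `n_retained`, `config`, `priors`, `dt`.
#' @export
run_sampler <- function(trace, priors = default_priors(),
                        config = sampler_config()) {
  stopifnot(inherits(trace, "pgbar_trace"), inherits(priors, "pgbar_priors"),
            inherits(config, "pgbar_config"))
  set.seed(config$seed)
  T_ <- length(trace$values)
  init <- initialize_sampler(trace, priors, config)
  theta <- init$theta
  x_ref <- init$x_ref

  mh_scales <- c(a_max = prior_sd(priors$a_max), tau_r = prior_sd(priors$tau_r),
                 tau_d = prior_sd(priors$tau_d), c0 = prior_sd(priors$c0)) *
    config$mh_scale_frac

  n_ret <- (config$n_iterations - config$burn_in) %/% config$thinning
  theta_names <- c("r0", "r1", "w01", "w10", "a_max", "tau_r", "tau_d", "c0",
                   "sigma2", "sigma2_b")
  theta_draws <- matrix(NA_real_, n_ret, length(theta_names),
                        dimnames = list(NULL, theta_names))
  spikes <- matrix(NA_integer_, n_ret, T_)
  states <- matrix(NA_integer_, n_ret, T_)
  baseline <- matrix(NA_real_, n_ret, T_)
  acc_sum <- c(a_max = 0, tau_r = 0, tau_d = 0, c0 = 0)
  acc_n <- 0L
  log_con <- if (!is.null(config$log_file)) file(config$log_file, "w")
             else NULL
  on.exit(if (!is.null(log_con)) close(log_con))

  kept <- 0L
  for (it in seq_len(config$n_iterations)) {
    step <- tryCatch(
      gibbs_step(trace, priors, config, theta, x_ref, mh_scales),
      error = function(e) stop("iteration ", it, ": ", conditionMessage(e)))
    theta <- step$theta
    x_ref <- step$x_ref

    if (config$adapt && it <= config$burn_in) {
      # Robbins-Monro toward ~30% acceptance, frozen after burn-in
      mh_scales <- mh_scales *
        exp((as.numeric(step$accepted) - 0.3) / sqrt(it + 10))
    }
    if (it > config$burn_in) {
      acc_sum <- acc_sum + step$accepted
      acc_n <- acc_n + 1L
      if ((it - config$burn_in) %% config$thinning == 0L && kept < n_ret) {
        kept <- kept + 1L
        theta_draws[kept, ] <- unlist(theta[theta_names])
        spikes[kept, ] <- x_ref$s
        states[kept, ] <- x_ref$q
        baseline[kept, ] <- x_ref$b
      }
    }
    if (!is.null(log_con) && (it %% 50L == 0L || it == config$n_iterations)) {
      writeLines(jsonlite::toJSON(list(
        iteration = it, theta = theta[theta_names],
        acceptance = as.list(step$accepted),
        ancestor_fallbacks = step$n_fallbacks), auto_unbox = TRUE), log_con)
    }
  }
  structure(list(theta = as.data.frame(theta_draws[seq_len(kept), ,
                                                   drop = FALSE]),
                 spikes = spikes[seq_len(kept), , drop = FALSE],
                 states = states[seq_len(kept), , drop = FALSE],
                 baseline = baseline[seq_len(kept), , drop = FALSE],
                 acceptance = if (acc_n > 0) acc_sum / acc_n else acc_sum,
                 n_retained = kept, config = config, priors = priors,
                 dt = trace$dt),
            class = "pgbar_samples")
}

#' @export
print.pgbar_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: %d retained draws, T = %d steps, dt = %.6g s\n",
              x$n_retained, ncol(x$spikes), x$dt))
  cat(sprintf("  mean total spikes %.2f; MH acceptance: %s\n",
              mean(rowSums(x$spikes)),
              paste(names(x$acceptance),
                    sprintf("%.2f", x$acceptance), collapse = ", ")))
  invisible(x)
}

#' Reconstruct calcium trajectories from posterior draws
#'
#' @param samples a `pgbar_samples` object.
#' @param draws indices of retained draws (default all).
#' @return Matrix (draws x T) of calcium levels.
#' @export
reconstruct_calcium <- function(samples, draws = seq_len(samples$n_retained)) {
  out <- matrix(NA_real_, length(draws), ncol(samples$spikes))
  for (k in seq_along(draws)) {
    i <- draws[k]
    th <- samples$theta[i, ]
    coeffs <- kinetics_to_ar(th$tau_r, th$tau_d, th$a_max, samples$dt)
    out[k, ] <- compute_calcium(samples$spikes[i, ], coeffs, th$c0)
  }
  out
}

# ---------------------------------------------------------------------------
# Geweke joint-distribution diagnostic
# ---------------------------------------------------------------------------

.geweke_stat_names <- c("r0", "r1", "w01", "w10", "a_max", "tau_r", "tau_d",
                        "c0", "sigma2", "sigma2_b", "total_spikes",
                        "mean_q", "mean_b", "mean_F")

.geweke_stats <- function(theta, sim_or_traj, values) {
  c(unlist(theta[c("r0", "r1", "w01", "w10", "a_max", "tau_r", "tau_d", "c0",
                   "sigma2", "sigma2_b")]),
    total_spikes = sum(sim_or_traj$s),
    mean_q = mean(sim_or_traj$q), mean_b = mean(sim_or_traj$b),
    mean_F = mean(values))
}

# Autocorrelation-robust standard error of the mean: batch means with an
# AR(1) inflation for residual batch-level correlation. The successive-
# conditional chain can have correlation times of hundreds of rounds (the
# baseline level is only weakly anchored by its initial-state prior), so a
# naive sqrt(n) batch scheme badly understates the error.
.batch_se <- function(x, nb = 50L) {
  n <- length(x)
  bs <- floor(n / nb)
  if (bs < 2) return(stats::sd(x) / sqrt(n))
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  rho <- suppressWarnings(stats::cor(bm[-1], bm[-nb]))
  if (!is.finite(rho)) rho <- 0
  rho <- min(max(rho, 0), 0.95)
  stats::sd(bm) / sqrt(nb) * sqrt((1 + rho) / (1 - rho))
}

#' Geweke getting-it-right check of the Gibbs sampler
#'
#' Compares the marginal distribution of `(theta, X, F)` under (a)
#' prior-predictive forward simulation and (b) the successive-conditional
#' chain that alternates one full Gibbs transition with re-simulation of the
#' data given the current latent state. For a correct sampler both target the
#' same joint distribution, so standardized differences of summary statistics
#' should be small; a broken sampler (see the `mutation` fixture of
#' [pgas_sweep()]) produces large `|z|`.
#'
#' @param priors a `pgbar_priors` object.
#' @param config a `pgbar_config` object (small `n_particles` is fine; the
#'   check is per-transition, not per-chain-length). Adaptation is forced off.
#' @param t_steps short trace length (<= 50 recommended).
#' @param dt sampling period (s).
#' @param n_rounds rounds per chain.
#' @param mutation weight-mutation fixture passed to the sweep (tests only).
#' @return A data.frame with one row per monitored statistic: means and
#'   autocorrelation-robust standard errors for both chains and the
#'   standardized difference `z`. Zero rounds give an empty frame.
#' @export
geweke_check <- function(priors, config, t_steps = 30L, dt = 0.01,
                         n_rounds = 1000L, mutation = 0L) {
  if (n_rounds == 0L)
    return(data.frame(stat = character(), mean_forward = numeric(),
                      mean_chain = numeric(), z = numeric()))
  config$adapt <- FALSE
  mh_scales <- c(a_max = prior_sd(priors$a_max), tau_r = prior_sd(priors$tau_r),
                 tau_d = prior_sd(priors$tau_d), c0 = prior_sd(priors$c0)) *
    config$mh_scale_frac

  ns <- length(.geweke_stat_names)
  fwd <- matrix(NA_real_, n_rounds, ns, dimnames = list(NULL,
                                                        .geweke_stat_names))
  chn <- matrix(NA_real_, n_rounds, ns, dimnames = list(NULL,
                                                        .geweke_stat_names))

  # (a) marginal-conditional: iid prior-predictive draws
  for (i in seq_len(n_rounds)) {
    th <- draw_theta_from_priors(priors, dt)
    sim <- simulate_trace(th, t_steps, dt)
    fwd[i, ] <- .geweke_stats(th, list(s = sim$spikes, q = sim$states,
                                       b = sim$baseline), sim$trace$values)
  }

  # (b) successive-conditional chain
  th <- draw_theta_from_priors(priors, dt)
  sim <- simulate_trace(th, t_steps, dt)
  traj <- list(q = sim$states, s = sim$spikes, c = sim$calcium,
               b = sim$baseline)
  values <- sim$trace$values
  for (i in seq_len(n_rounds)) {
    trace <- fluorescence_trace(values, dt)
    step <- gibbs_step(trace, priors, config, th, traj, mh_scales,
                       mutation = mutation)
    th <- step$theta
    traj <- step$x_ref
    # re-simulate the observations given the latent state and theta
    values <- traj$c + traj$b + stats::rnorm(t_steps, 0, sqrt(th$sigma2))
    chn[i, ] <- .geweke_stats(th, traj, values)
  }

  z <- vapply(seq_len(ns), function(j) {
    se <- sqrt(stats::sd(fwd[, j])^2 / n_rounds + .batch_se(chn[, j])^2)
    (mean(fwd[, j]) - mean(chn[, j])) / se
  }, numeric(1))
  data.frame(stat = .geweke_stat_names,
             mean_forward = colMeans(fwd), se_forward = apply(fwd, 2,
                                                              stats::sd) /
               sqrt(n_rounds),
             mean_chain = colMeans(chn),
             se_chain = apply(chn, 2, .batch_se),
             z = z, row.names = NULL)
}
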