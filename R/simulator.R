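#' Forward-simulate the generative model
#'
#' Samples a fluorescence trace with full ground truth from the bursting
#' autoregressive model: a two-state firing regime chain (per-step switching
#' probabilities `w*dt`), Poisson spike counts at the regime's rate, a
#' deterministic AR(2) calcium response, a Gaussian random-walk baseline
#' (`b_1 ~ N(0,1)`, increments `N(0, sigma2_b*dt)`) and iid Gaussian
#' observation noise.
#'
#' @param theta a `pgbar_theta` object.
#' @param t_steps number of time steps, `>= 2`.
#' @param dt sampling period (s); requires `w01*dt < 1` and `w10*dt < 1`.
#' @param seed optional integer seed (sets the R RNG for reproducibility).
#' @param pin_baseline start the baseline at exactly 0 instead of `N(0,1)`
#'   (clean fixtures; default `FALSE`).
#' @return An object of class `pgbar_sim`: list with `trace`
#'   (a [fluorescence_trace()]), `spikes`, `states`, `calcium`, `baseline`,
#'   `noise` (all length `t_steps`), `theta` and `seed`.
#' @export
simulate_trace <- function(theta, t_steps, dt, seed = NULL,
                           pin_baseline = FALSE) {
  validate_theta_dt(theta, dt)
  if (t_steps < 2) stop("t_steps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  t_steps <- as.integer(t_steps)

  q <- integer(t_steps)
  q[1] <- as.integer(stats::runif(1) < 0.5)
  p01 <- theta$w01 * dt
  p10 <- theta$w10 * dt
  u <- stats::runif(t_steps - 1L)
  for (t in 2:t_steps) {
    q[t] <- if (q[t - 1L] == 0L) as.integer(u[t - 1L] < p01)
            else as.integer(u[t - 1L] >= p10)
  }
  s <- stats::rpois(t_steps, ifelse(q == 1L, theta$r1, theta$r0) * dt)
  .assemble_sim(theta, s, q, t_steps, dt, seed, pin_baseline)
}

#' Simulate a trace with clamped spike times
#'
#' Same observation model as [simulate_trace()] but the spike train is fixed:
#' one spike per listed time, clamped to the nearest sampling step (ties go to
#' the later step); duplicate times mapping to the same step are summed. Used
#' for two-spike short-interval and fixed Poisson-train fixtures.
#'
#' @param spike_times spike times (s), within `[0, t_steps*dt)`.
#' @param theta a `pgbar_theta` object.
#' @param t_steps number of time steps.
#' @param dt sampling period (s).
#' @param seed optional integer seed.
#' @param pin_baseline start the baseline at exactly 0 (default `TRUE`:
#'   stimulus fixtures are cleaner when they start on the axis).
#' @return A `pgbar_sim` object; `states` is all zeros (regime is not
#'   simulated when spikes are clamped).
#' @export
simulate_stimulus_trace <- function(spike_times, theta, t_steps, dt,
                                    seed = NULL, pin_baseline = TRUE) {
  validate_theta_dt(theta, dt)
  if (t_steps < 2) stop("t_steps must be >= 2")
  t_steps <- as.integer(t_steps)
  if (length(spike_times) > 0 &&
      (any(spike_times < 0) || any(spike_times >= t_steps * dt)))
    stop("spike times must lie within the trace duration")
  if (!is.null(seed)) set.seed(seed)
  s <- integer(t_steps)
  if (length(spike_times) > 0) {
    # time 0 is the start of step 1; clamp to nearest step center boundary,
    # ties to the later step
    steps <- pmin(pmax(floor(spike_times / dt + 0.5), 0), t_steps - 1L) + 1L
    tab <- table(steps)
    s[as.integer(names(tab))] <- as.integer(tab)
  }
  q <- integer(t_steps)
  .assemble_sim(theta, s, q, t_steps, dt, seed, pin_baseline)
}

.assemble_sim <- function(theta, s, q, t_steps, dt, seed, pin_baseline) {
  coeffs <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  calcium <- compute_calcium(s, coeffs, theta$c0)
  b1 <- if (pin_baseline) 0 else stats::rnorm(1)
  baseline <- cumsum(c(b1, stats::rnorm(t_steps - 1L, 0,
                                        sqrt(theta$sigma2_b * dt))))
  noise <- stats::rnorm(t_steps, 0, sqrt(theta$sigma2))
  values <- calcium + baseline + noise
  structure(list(trace = fluorescence_trace(values, dt),
                 spikes = as.integer(s), states = as.integer(q),
                 calcium = calcium, baseline = baseline, noise = noise,
                 theta = theta, seed = seed),
            class = "pgbar_sim")
}

#' @export
print.pgbar_sim <- function(x, ...) {
  cat(sprintf("Simulated trace: T = %d, dt = %.6g s, %d spikes, %.1f%% burst occupancy\n",
              length(x$trace$values), x$trace$dt, sum(x$spikes),
              100 * mean(x$states)))
  invisible(x)
}

#' Signal-to-noise ratio of a parameter set
#'
#' Ratio between the unitary peak response `a_max` and the observation-noise
#' standard deviation `sigma`.
#'
#' @param theta a `pgbar_theta` object.
#' @return Scalar SNR.
#' @export
snr <- function(theta) {
  if (theta$sigma2 <= 0) stop("sigma2 must be positive")
  theta$a_max / sqrt(theta$sigma2)
}

#' Standardized noise level of a trace
#'
#' Standard deviation of the normalized fluorescence divided by the square
#' root of the sampling frequency; a noise index comparable across frame
#' rates.
#'
#' @param trace a `pgbar_trace` object.
#' @return Scalar noise index.
#' @export
standardized_noise <- function(trace) {
  stats::sd(trace$values) / sqrt(1 / trace$dt)
}

#' Write a simulation fixture to disk
#'
#' Writes `trace.csv` (time, fluorescence), `truth.csv` (time, spikes, q,
#' calcium, baseline) and `meta.json` (theta, seed, dt) into `dir`.
#'
#' @param sim a `pgbar_sim` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tm <- (seq_along(sim$trace$values) - 1L) * sim$trace$dt
  p1 <- file.path(dir, "trace.csv")
  p2 <- file.path(dir, "truth.csv")
  p3 <- file.path(dir, "meta.json")
  data.table::fwrite(data.table::data.table(time = tm,
                                            fluorescence = sim$trace$values),
                     p1)
  data.table::fwrite(data.table::data.table(time = tm, spikes = sim$spikes,
                                            q = sim$states,
                                            calcium = sim$calcium,
                                            baseline = sim$baseline), p2)
  jsonlite::write_json(list(theta = unclass(sim$theta), seed = sim$seed,
                            dt = sim$trace$dt),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
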