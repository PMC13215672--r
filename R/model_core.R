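#' Time-independent model parameters
#'
#' Bundles the parameter vector theta of the bursting autoregressive
#' fluorescence model: two Poisson firing rates (a baseline regime and a burst
#' regime), the switching rates of the two-state firing process, the unitary
#' calcium response kinetics (peak amplitude, rise and decay time), the initial
#' calcium level, the observation-noise variance and the baseline random-walk
#' variance rate.
#'
#' @param r0 baseline firing rate (Hz), `>= 0`.
#' @param r1 burst firing rate (Hz), `>= 0`.
#' @param w01 burst-onset switching rate (Hz), `>= 0`.
#' @param w10 burst-offset switching rate (Hz), `>= 0`.
#' @param a_max unitary peak fluorescence response (dF/F units), `> 0`.
#' @param tau_r rise time, i.e. time to peak of the unitary response (s).
#' @param tau_d asymptotic decay time constant of the unitary response (s);
#'   must exceed `tau_r`.
#' @param c0 initial calcium level (dF/F units).
#' @param sigma2 observation-noise variance, `> 0`.
#' @param sigma2_b baseline random-walk variance rate (variance per second),
#'   `>= 0`.
#' @return An object of class `pgbar_theta` (a named list).
#' @export
model_parameters <- function(r0, r1, w01, w10, a_max, tau_r, tau_d, c0,
                             sigma2, sigma2_b) {
  th <- list(r0 = r0, r1 = r1, w01 = w01, w10 = w10, a_max = a_max,
             tau_r = tau_r, tau_d = tau_d, c0 = c0, sigma2 = sigma2,
             sigma2_b = sigma2_b)
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  if (r0 < 0 || r1 < 0 || w01 < 0 || w10 < 0)
    stop("rates r0, r1, w01, w10 must be non-negative")
  if (a_max <= 0) stop("a_max must be positive")
  if (tau_r <= 0 || tau_r >= tau_d)
    stop("rise/decay times must satisfy 0 < tau_r < tau_d")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (sigma2_b < 0) stop("sigma2_b must be non-negative")
  structure(th, class = "pgbar_theta")
}

#' @export
print.pgbar_theta <- function(x, ...) {
  cat("Model parameters (pgbar_theta):\n")
  cat(sprintf("  firing rates      r0 = %.4g Hz, r1 = %.4g Hz\n", x$r0, x$r1))
  cat(sprintf("  switching rates   w01 = %.4g Hz, w10 = %.4g Hz\n", x$w01, x$w10))
  cat(sprintf("  kernel            a_max = %.4g, tau_r = %.4g s, tau_d = %.4g s\n",
              x$a_max, x$tau_r, x$tau_d))
  cat(sprintf("  c0 = %.4g, sigma2 = %.4g, sigma2_b = %.4g /s\n",
              x$c0, x$sigma2, x$sigma2_b))
  invisible(x)
}

# Check the per-step switching probabilities are valid for a sampling period.
validate_theta_dt <- function(theta, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (theta$w01 * dt >= 1 || theta$w10 * dt >= 1)
    stop("switching probabilities w*dt must be < 1 for the working dt")
  invisible(TRUE)
}

#' Fluorescence trace container
#'
#' @param values numeric vector of dF/F observations (length `T >= 2`).
#' @param dt sampling period (s), `> 0`.
#' @return An object of class `pgbar_trace`.
#' @export
fluorescence_trace <- function(values, dt) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a trace needs at least 2 observations")
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar")
  structure(list(values = values, dt = dt), class = "pgbar_trace")
}

#' @export
print.pgbar_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: T = %d steps, dt = %.6g s (%.6g Hz), %.4g s total\n",
              length(x$values), x$dt, 1 / x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' Per-time-step latent state
#'
#' The hidden state at one time step: firing regime `q` (0 = baseline, 1 =
#' burst), spike count `s`, calcium pair `c_vec = c(c_t, c_tm1)` and baseline
#' level `b`.
#'
#' @param q firing regime, 0 or 1.
#' @param s spike count, non-negative integer.
#' @param c_vec numeric length-2 vector `(c_t, c_{t-1})`.
#' @param b baseline level.
#' @return An object of class `pgbar_state`.
#' @export
latent_state <- function(q, s, c_vec, b) {
  if (!q %in% c(0, 1)) stop("q must be 0 or 1")
  if (s < 0 || s != round(s)) stop("s must be a non-negative integer")
  if (length(c_vec) != 2L || any(!is.finite(c_vec)))
    stop("c_vec must be a finite length-2 vector")
  if (!is.finite(b)) stop("b must be finite")
  structure(list(q = as.integer(q), s = as.integer(s),
                 c_vec = as.numeric(c_vec), b = as.numeric(b)),
            class = "pgbar_state")
}

# ---------------------------------------------------------------------------
# Kinetic reparameterization
# ---------------------------------------------------------------------------

# f(x) = log(x)/(x-1), strictly decreasing on (1, Inf) with range (0, 1).
.f_ratio <- function(x) log(x) / (x - 1)

#' Convert kinetic parameters to AR(2) coefficients
#'
#' Maps phenomenological kinetics (rise time `tau_r`, decay time `tau_d`, peak
#' amplitude `a_max`) of the unitary calcium response into the coefficients of
#' the discrete second-order autoregressive kernel at sampling period `dt`.
#' The ratio of the log-roots `x = g_-/g_+ > 1` solves
#' `log(x)/(x-1) = tau_r/tau_d` (bracketed root-finding); then
#' `g_+ = -dt/tau_d`, `g_- = g_+ * x`, `gamma_1 = e^{g_+} + e^{g_-}`,
#' `gamma_2 = -e^{g_+ + g_-}`, and the per-spike increment is
#' `a = a_max / g_a` where `g_a` converts the increment to the continuous-time
#' peak of the kernel.
#'
#' @param tau_r rise time (s), `0 < tau_r < tau_d`.
#' @param tau_d decay time (s).
#' @param a_max unitary peak response (dF/F units).
#' @param dt sampling period (s).
#' @param tol root-finder tolerance on `x`.
#' @return An object of class `pgbar_kernel` with fields `gamma1`, `gamma2`,
#'   `a` (per-spike increment), `g_plus`, `g_minus` (per-step log roots,
#'   negative), `g_a` and `dt`.
#' @export
kinetics_to_ar <- function(tau_r, tau_d, a_max, dt, tol = 1e-10) {
  if (!(tau_r > 0 && tau_r < tau_d)) stop("need 0 < tau_r < tau_d")
  if (dt <= 0) stop("dt must be positive")
  if (a_max <= 0) stop("a_max must be positive")
  target <- tau_r / tau_d
  # f is monotone decreasing from 1 (x -> 1+) to 0 (x -> Inf); bracket upward.
  lo <- 1 + 1e-12
  hi <- 2
  while (.f_ratio(hi) > target && hi < 1e6) hi <- hi * 2
  if (.f_ratio(hi) > target)
    stop("root-finder bracketing failed: tau_r/tau_d = ", signif(target, 6),
         " too close to 1 (near-repeated roots)")
  r <- tryCatch(
    stats::uniroot(function(x) .f_ratio(x) - target, c(lo, hi), tol = tol),
    error = function(e) stop("root-finder failed for tau_r/tau_d = ",
                             signif(target, 6), ": ", conditionMessage(e)))
  x <- r$root
  g_plus <- -dt / tau_d       # per-step, negative
  g_minus <- g_plus * x       # more negative
  gamma1 <- exp(g_plus) + exp(g_minus)
  gamma2 <- -exp(g_plus + g_minus)
  g_a <- .g_amplitude(g_plus, g_minus)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, a = a_max / g_a,
                 g_plus = g_plus, g_minus = g_minus, g_a = g_a, dt = dt),
            class = "pgbar_kernel")
}

# Peak of the continuous-time kernel A*(e^{g+ t} - e^{g- t})/(gamma+ - gamma-)
# relative to the per-spike increment A. With u = g+/g- in (0,1) the peak time
# is t* = log(u)/(g- - g+) and the peak value is
# A * u^{u/(1-u)} * (1-u) / (e^{g+} - e^{g-}).
.g_amplitude <- function(g_plus, g_minus) {
  u <- g_plus / g_minus
  u^(u / (1 - u)) * (1 - u) / (exp(g_plus) - exp(g_minus))
}

#' Convert AR(2) coefficients back to kinetic parameters
#'
#' Inverse of [kinetics_to_ar()]. The AR roots are
#' `gamma_pm = (gamma1 +- sqrt(gamma1^2 + 4*gamma2))/2`; with
#' `g_pm = log(gamma_pm)` the rise time is `log(g_+/g_-)/(g_- - g_+)` steps and
#' the decay time `-1/g_+` steps, both converted to seconds with `dt`.
#'
#' @param coeffs a `pgbar_kernel` object, or a list with at least `gamma1`,
#'   `gamma2` and `a`.
#' @param dt sampling period (s).
#' @return Named list `a_max`, `tau_r`, `tau_d` (seconds).
#' @export
ar_to_kinetics <- function(coeffs, dt) {
  gamma1 <- coeffs$gamma1
  gamma2 <- coeffs$gamma2
  disc <- gamma1^2 + 4 * gamma2
  if (!is.finite(disc) || disc <= 0)
    stop("complex or repeated AR roots: gamma1^2 + 4*gamma2 must be > 0")
  root_p <- (gamma1 + sqrt(disc)) / 2
  # small root via the root product gamma_+ * gamma_- = -gamma2: avoids the
  # catastrophic cancellation of (gamma1 - sqrt(disc))/2 when the roots are
  # orders of magnitude apart
  root_m <- -gamma2 / root_p
  if (root_m <= 0 || root_p >= 1)
    stop("AR roots must lie in (0, 1); got (", signif(root_m, 6), ", ",
         signif(root_p, 6), ")")
  g_plus <- log(root_p)
  g_minus <- log(root_m)
  tau_r <- log(g_plus / g_minus) / (g_minus - g_plus) * dt
  tau_d <- -1 / g_plus * dt
  list(a_max = coeffs$a * .g_amplitude(g_plus, g_minus),
       tau_r = tau_r, tau_d = tau_d)
}

#' Single-spike calcium kernel response
#'
#' Calcium level `c_t` for `t = 1..t_max` following a single spike at `t = 1`
#' with zero initial calcium: the closed form
#' `c_t = a * (gamma_+^t - gamma_-^t)/(gamma_+ - gamma_-)`, identical to
#' iterating the AR(2) recursion.
#'
#' @param coeffs a `pgbar_kernel` object.
#' @param t_max number of steps, `>= 1`.
#' @return Numeric vector of length `t_max`.
#' @export
kernel_response <- function(coeffs, t_max) {
  if (t_max < 1) stop("t_max must be >= 1")
  root_p <- exp(coeffs$g_plus)
  root_m <- exp(coeffs$g_minus)
  tt <- seq_len(t_max)
  coeffs$a * (root_p^tt - root_m^tt) / (root_p - root_m)
}

# Recompute a calcium trajectory from a spike-count sequence (AR(2) recursion,
# c_1 = c0 + a*s_1). Deterministic given spikes, kinetics and c0.
compute_calcium <- function(s, coeffs, c0) {
  e <- coeffs$a * s
  e[1L] <- e[1L] + c0
  as.numeric(stats::filter(e, c(coeffs$gamma1, coeffs$gamma2),
                           method = "recursive", init = c(0, 0)))
}

# ---------------------------------------------------------------------------
# Model densities
# ---------------------------------------------------------------------------

# Per-step switching probability matrix; rows = q_{t-1}, cols = q_t.
transition_matrix <- function(theta, dt) {
  matrix(c(1 - theta$w01 * dt, theta$w01 * dt,
           theta$w10 * dt, 1 - theta$w10 * dt),
         nrow = 2, byrow = TRUE)
}

#' Log-density of a latent-state transition (stochastic components)
#'
#' Evaluates the stochastic factors of the latent transition density: the
#' firing-state switching probability, the Poisson spike-count mass and the
#' Gaussian baseline increment. The deterministic calcium propagation
#' `c_vec = M c_vec_prev + a*(s, 0)` is a structural constraint checked as a
#' precondition, never a density factor.
#'
#' @param x_prev,x `pgbar_state` objects at times `t-1` and `t`.
#' @param theta a `pgbar_theta` object.
#' @param coeffs a `pgbar_kernel` object (for the calcium consistency check).
#' @param dt sampling period (s).
#' @param check_calcium verify the calcium constraint (default `TRUE`).
#' @return Log-density (scalar).
#' @export
transition_logdensity <- function(x_prev, x, theta, coeffs, dt,
                                  check_calcium = TRUE) {
  validate_theta_dt(theta, dt)
  if (check_calcium) {
    expected <- c(coeffs$gamma1 * x_prev$c_vec[1] +
                    coeffs$gamma2 * x_prev$c_vec[2] + coeffs$a * x$s,
                  x_prev$c_vec[1])
    if (max(abs(x$c_vec - expected)) > 1e-8 * max(1, abs(expected[1])))
      stop("calcium consistency violated: c_vec != M c_vec_prev + a*(s, 0)")
  }
  w <- transition_matrix(theta, dt)
  r <- if (x$q == 1L) theta$r1 else theta$r0
  log(w[x_prev$q + 1L, x$q + 1L]) +
    stats::dpois(x$s, r * dt, log = TRUE) +
    stats::dnorm(x$b, x_prev$b, sqrt(theta$sigma2_b * dt), log = TRUE)
}

#' Log-density of a fluorescence observation
#'
#' `log N(f; c_t + b_t, sigma^2)`.
#'
#' @param f observed fluorescence value.
#' @param x a `pgbar_state` object.
#' @param theta a `pgbar_theta` object.
#' @return Log-density (scalar).
#' @export
observation_logdensity <- function(f, x, theta) {
  stats::dnorm(f, x$c_vec[1] + x$b, sqrt(theta$sigma2), log = TRUE)
}

#' Convolution of two Gaussian densities
#'
#' The integral `I(y1, y2, v1, v2) = int N(x; y1, v1) N(x; y2, v2) dx`,
#' available in closed form as a Gaussian in `y1 - y2` with variance
#' `v1 + v2`. This is the building block of the optimal proposal: it
#' marginalizes the baseline analytically.
#'
#' @param y1,y2 means.
#' @param v1,v2 variances, `> 0`.
#' @param log return the log value.
#' @return Density value (or log-density).
#' @export
gaussian_convolution <- function(y1, y2, v1, v2, log = FALSE) {
  if (any(v1 <= 0) || any(v2 <= 0)) stop("variances must be positive")
  lv <- -0.5 * (y1 - y2)^2 / (v1 + v2) - 0.5 * base::log(2 * pi * (v1 + v2))
  if (log) lv else exp(lv)
}

#' Log-density of the initial latent state
#'
#' At `t = 1` the two firing regimes have equal probability, the spike count is
#' Poisson with the regime's rate, the baseline is standard normal and the
#' calcium pair is constrained to `(c0 + a*s1, 0)`.
#'
#' @param x1 a `pgbar_state` object.
#' @param theta a `pgbar_theta` object.
#' @param coeffs a `pgbar_kernel` object.
#' @param dt sampling period (s).
#' @param check_calcium verify the initial calcium constraint.
#' @return Log-density (scalar).
#' @export
initial_logdensity <- function(x1, theta, coeffs, dt, check_calcium = TRUE) {
  if (check_calcium) {
    expected <- c(theta$c0 + coeffs$a * x1$s, 0)
    if (max(abs(x1$c_vec - expected)) > 1e-8 * max(1, abs(expected[1])))
      stop("initial calcium constraint violated: c_vec != (c0 + a*s1, 0)")
  }
  r <- if (x1$q == 1L) theta$r1 else theta$r0
  log(0.5) + stats::dpois(x1$s, r * dt, log = TRUE) +
    stats::dnorm(x1$b, 0, 1, log = TRUE)
}
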