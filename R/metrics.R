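#' Summarize posterior samples
#'
#' Per-step posterior means and standard deviations of spike counts, burst
#' probability and baseline, plus per-bin spike-count posterior distributions
#' for a chosen bin width.
#'
#' @param samples a `pgbar_samples` object.
#' @param bin_width bin width (s) for the per-bin spike-count distributions.
#' @return An object of class `pgbar_summary`: list with `mean_spikes`,
#'   `sd_spikes`, `burst_prob`, `mean_baseline`, `sd_baseline` (length `T`),
#'   `bin_counts` (draws x n_bins matrix of binned counts), `bin_edges`, and
#'   `bin_dist` (list of normalized count distributions per bin).
#' @export
summarize_samples <- function(samples, bin_width = 1) {
  if (!inherits(samples, "pgbar_samples")) stop("need a pgbar_samples object")
  if (samples$n_retained < 1) stop("empty posterior sample set")
  T_ <- ncol(samples$spikes)
  dt <- samples$dt
  steps_per_bin <- max(1L, round(bin_width / dt))
  bin_id <- ((seq_len(T_) - 1L) %/% steps_per_bin) + 1L
  n_bins <- max(bin_id)
  bin_counts <- t(apply(samples$spikes, 1,
                        function(s) tapply(s, bin_id, sum)))
  if (n_bins == 1L) bin_counts <- matrix(bin_counts, ncol = 1L)
  bin_dist <- lapply(seq_len(n_bins), function(b) {
    tab <- table(bin_counts[, b])
    p <- as.numeric(tab) / sum(tab)
    stats::setNames(p, names(tab))
  })
  structure(list(
    mean_spikes = colMeans(samples$spikes),
    sd_spikes = apply(samples$spikes, 2, stats::sd),
    burst_prob = colMeans(samples$states),
    mean_baseline = colMeans(samples$baseline),
    sd_baseline = apply(samples$baseline, 2, stats::sd),
    bin_counts = bin_counts,
    bin_edges = seq(0, n_bins) * steps_per_bin * dt,
    bin_dist = bin_dist, dt = dt), class = "pgbar_summary")
}

# Gaussian-smooth a per-step signal; bandwidth = kernel standard deviation.
.gauss_smooth <- function(x, dt, bandwidth) {
  sd_steps <- bandwidth / dt
  half <- max(1L, ceiling(4 * sd_steps))
  k <- stats::dnorm(seq(-half, half), sd = sd_steps)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Correlation of Gaussian-filtered spike signals
#'
#' Pearson correlation of the two signals after smoothing each with a
#' Gaussian kernel; `bandwidth` is the kernel standard deviation (200 ms in
#' benchmark-style comparisons, 20 ms for fast-indicator analyses).
#'
#' @param est,truth per-step spike counts (equal length).
#' @param dt sampling period (s).
#' @param bandwidth Gaussian kernel sd (s), `> 0`.
#' @return Pearson correlation; `NA` with a warning if a smoothed signal has
#'   zero variance.
#' @export
filtered_correlation <- function(est, truth, dt, bandwidth = 0.2) {
  if (length(est) != length(truth)) stop("signals must have equal length")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  a <- .gauss_smooth(est, dt, bandwidth)
  b <- .gauss_smooth(truth, dt, bandwidth)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance smoothed signal; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Average absolute error and bias of spike-count estimates
#'
#' Average error is the sum of absolute deviations from the true per-step
#' counts divided by the number of time steps; bias is the signed average
#' deviation.
#'
#' @param est per-step posterior mean spike counts.
#' @param truth per-step true counts.
#' @return Named list `error`, `bias`.
#' @export
error_and_bias <- function(est, truth) {
  if (length(est) != length(truth)) stop("signals must have equal length")
  list(error = mean(abs(est - truth)), bias = mean(est - truth))
}

#' Posterior distribution of the inter-spike interval
#'
#' For each retained draw, measures the interval between the first two spike
#' events inside a time window. Draws without exactly two events in the
#' window are excluded from the ISI histogram but tallied in a spike-count
#' side distribution. The mode is computed on a binned histogram (3 ms bins
#' by default).
#'
#' @param samples a `pgbar_samples` object.
#' @param window length-2 numeric, window `(start, end)` in seconds.
#' @param bin_width_ms histogram bin width for the mode (ms).
#' @return List with `isi_ms` (per qualifying draw, ms), `mode_ms` (`NA` if
#'   no draw has two spikes in the window), `two_spike_fraction`,
#'   `count_dist` (distribution of the number of events in the window).
#' @export
isi_posterior <- function(samples, window, bin_width_ms = 3) {
  dt <- samples$dt
  T_ <- ncol(samples$spikes)
  i0 <- max(1L, floor(window[1] / dt) + 1L)
  i1 <- min(T_, ceiling(window[2] / dt))
  if (i0 >= i1) stop("window outside the trace")
  sub <- samples$spikes[, i0:i1, drop = FALSE]
  n_events <- rowSums(sub)
  isi <- rep(NA_real_, nrow(sub))
  for (i in which(n_events >= 2)) {
    st <- rep(seq_len(ncol(sub)), sub[i, ])  # expand counts to event steps
    isi[i] <- (st[2] - st[1]) * dt * 1000
  }
  keep <- which(n_events == 2)
  isi_ms <- isi[keep]
  mode_ms <- NA_real_
  if (length(isi_ms) > 0) {
    br <- seq(0, max(isi_ms) + bin_width_ms, by = bin_width_ms)
    h <- graphics::hist(isi_ms, breaks = br, plot = FALSE)
    mode_ms <- h$mids[which.max(h$counts)]
  }
  tab <- table(n_events)
  list(isi_ms = isi_ms, mode_ms = mode_ms,
       two_spike_fraction = mean(n_events == 2),
       count_dist = stats::setNames(as.numeric(tab) / sum(tab), names(tab)))
}

#' Point detections from posterior spike probabilities
#'
#' Steps whose posterior spike probability exceeds the threshold are merged
#' into events (adjacent supra-threshold steps form one event located at the
#' probability-weighted center).
#'
#' @param samples a `pgbar_samples` object.
#' @param threshold posterior probability threshold (default 0.5).
#' @return Numeric vector of detected event times (s).
#' @export
detect_spikes <- function(samples, threshold = 0.5) {
  p <- colMeans(samples$spikes > 0)
  above <- p > threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  vapply(idx, function(k) {
    steps <- starts[k]:ends[k]
    sum((steps - 1) * samples$dt * p[steps]) / sum(p[steps])
  }, numeric(1))
}

#' Temporal accuracy and false detection rate
#'
#' Temporal accuracy is the mean over ground-truth spikes of the absolute
#' offset to the nearest detection; the false detection rate is
#' `(n_detected - n_truth) / n_truth`.
#'
#' @param samples a `pgbar_samples` object.
#' @param truth_times ground-truth spike times (s), non-empty.
#' @param threshold detection threshold, see [detect_spikes()].
#' @return Named list `accuracy` (s), `false_detection_rate`, `n_detected`.
#'   With no detections, accuracy is `NA` and the rate is `-1` (flagged by a
#'   warning).
#' @export
detection_metrics <- function(samples, truth_times, threshold = 0.5) {
  if (length(truth_times) == 0) stop("truth_times must be non-empty")
  det <- detect_spikes(samples, threshold)
  if (length(det) == 0) {
    warning("no detections above threshold")
    return(list(accuracy = NA_real_, false_detection_rate = -1,
                n_detected = 0L))
  }
  acc <- mean(vapply(truth_times, function(t0) min(abs(det - t0)),
                     numeric(1)))
  list(accuracy = acc,
       false_detection_rate = (length(det) - length(truth_times)) /
         length(truth_times),
       n_detected = length(det))
}

#' Correlation between event trains across bin sizes
#'
#' Bins both event-time sets at each bin size and reports the Pearson
#' correlation of the binned count vectors.
#'
#' @param est_times,truth_times event times (s).
#' @param duration total duration (s) defining the binning range.
#' @param bin_sizes_ms bin sizes (ms), default 2-50 ms.
#' @return data.frame with `bin_ms` and `correlation` (`NA` where a binned
#'   vector has zero variance).
#' @export
correlation_vs_binsize <- function(est_times, truth_times, duration,
                                   bin_sizes_ms = c(2, 5, 10, 20, 50)) {
  if (any(bin_sizes_ms <= 0)) stop("bin sizes must be positive")
  corr <- vapply(bin_sizes_ms, function(bm) {
    br <- seq(0, duration + bm / 1000, by = bm / 1000)
    a <- graphics::hist(est_times, breaks = br, plot = FALSE)$counts
    b <- graphics::hist(truth_times, breaks = br, plot = FALSE)$counts
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  data.frame(bin_ms = bin_sizes_ms, correlation = corr)
}

#' Sum-pool spike counts to a coarser rate
#'
#' @param counts per-step counts.
#' @param dt sampling period (s).
#' @param target_rate target sampling rate (Hz), `<= 1/dt`.
#' @return Coarser count vector (window sums; the last partial window is
#'   kept).
#' @export
downsample_counts <- function(counts, dt, target_rate) {
  if (target_rate > 1 / dt + 1e-9) stop("target rate exceeds sampling rate")
  steps <- max(1L, round(1 / (target_rate * dt)))
  if (steps == 1L) return(counts)
  bin_id <- ((seq_along(counts) - 1L) %/% steps) + 1L
  as.numeric(tapply(counts, bin_id, sum))
}

#' Write metrics in tidy long form
#'
#' @param metrics named list of scalar metrics.
#' @param path output CSV path.
#' @param parameters optional named list recorded alongside each metric.
#' @return Invisibly, the path.
#' @export
write_metrics <- function(metrics, path, parameters = list()) {
  dt_ <- data.table::data.table(
    metric = names(metrics), value = as.numeric(unlist(metrics)),
    parameters = jsonlite::toJSON(parameters, auto_unbox = TRUE))
  data.table::fwrite(dt_, path)
  invisible(path)
}
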