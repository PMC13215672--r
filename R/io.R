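#' Read a fluorescence trace from CSV/TSV
#'
#' Accepts a single numeric column (requires `dt`) or two columns
#' `(time, value)` with `dt` inferred from the median spacing; timestamps
#' must be uniform to within `1e-6` relative tolerance.
#'
#' @param path file path (CSV or TSV, header optional).
#' @param dt sampling period (s); required for one-column files, overrides
#'   the time column otherwise.
#' @return A `pgbar_trace` object.
#' @export
read_trace <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(data.table::fread(path, header = "auto"),
                 error = function(e) stop("could not parse ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 1 || ncol(df) > 2)
    stop("expected a one- or two-column file, got ", ncol(df), " columns")
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop("non-numeric value in column ", j, " near line ", bad)
    }
  }
  if (ncol(df) == 1L) {
    if (is.null(dt)) stop("one-column trace requires an explicit dt")
    return(fluorescence_trace(df[[1]], dt))
  }
  tm <- df[[1]]
  if (is.null(dt)) {
    gaps <- diff(tm)
    dt <- stats::median(gaps)
    worst <- which.max(abs(gaps - dt))
    if (max(abs(gaps - dt)) > 1e-6 * dt)
      stop("non-uniform timestamps: worst gap ", signif(gaps[worst], 8),
           " s between rows ", worst, " and ", worst + 1L,
           " (expected ", signif(dt, 8), " s)")
  }
  fluorescence_trace(df[[2]], dt)
}

#' Write a fluorescence trace to CSV
#'
#' Two columns `time, fluorescence`, written at full precision so that
#' `read_trace(write_trace(x))` round-trips.
#'
#' @param trace a `pgbar_trace` object.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, path) {
  tm <- (seq_along(trace$values) - 1L) * trace$dt
  utils::write.csv(data.frame(time = format(tm, digits = 17),
                              fluorescence = format(trace$values,
                                                    digits = 17)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_prior_builders <- list(
  "truncated-normal" = function(h) tnorm_prior(h$mean, h$sd,
                                               lower = h$lower %||% 0,
                                               upper = h$upper %||% Inf),
  "gamma" = function(h) gamma_prior(h$shape, h$rate),
  "inverse-gamma" = function(h) invgamma_prior(h$shape, h$rate))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a configuration file
#'
#' JSON with two top-level sections: `priors` (science: one entry per model
#' parameter with `family` and hyperparameters) and `sampler` (engineering:
#' iteration counts, particles, seed, flags). Omitted entries fall back to
#' the documented defaults; unknown keys are rejected. See the shipped
#' `inst/extdata/default_config.json` for the schema with every field.
#'
#' @param path JSON config path (use `NULL` for all defaults).
#' @return List with `priors` (`pgbar_priors`) and `config` (`pgbar_config`).
#' @export
load_config <- function(path = NULL) {
  pr_defaults <- default_priors()
  if (is.null(path))
    return(list(priors = pr_defaults, config = sampler_config()))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), c("priors", "sampler"))
  if (length(bad)) stop("unknown top-level config keys: ",
                        paste(bad, collapse = ", "))
  pr_list <- unclass(pr_defaults)
  if (!is.null(raw$priors)) {
    bad <- setdiff(names(raw$priors), names(.prior_families))
    if (length(bad)) stop("unknown prior entries: ",
                          paste(bad, collapse = ", "))
    for (nm in names(raw$priors)) {
      h <- raw$priors[[nm]]
      fam <- h$family %||% .prior_families[[nm]]
      if (fam != .prior_families[[nm]])
        stop("parameter '", nm, "' requires a ", .prior_families[[nm]],
             " prior, got '", fam, "'")
      pr_list[[nm]] <- .config_prior_builders[[fam]](h)
    }
  }
  priors <- do.call(prior_spec, pr_list)
  cfg_args <- raw$sampler %||% list()
  known <- names(formals(sampler_config))
  bad <- setdiff(names(cfg_args), known)
  if (length(bad)) stop("unknown sampler config keys: ",
                        paste(bad, collapse = ", "))
  config <- do.call(sampler_config, cfg_args)
  list(priors = priors, config = config)
}

#' Write posterior samples and a run manifest
#'
#' Writes `theta.csv` (one row per retained draw), `spikes.csv` (sparse:
#' iteration, step, count), `summary.csv` (per-step posterior means/sds) and
#' `manifest.json` into `outdir`.
#'
#' @param samples a `pgbar_samples` object.
#' @param outdir output directory (created if missing).
#' @param input_path optional path of the input trace, recorded with its MD5
#'   checksum in the manifest.
#' @return Invisibly, the output directory.
#' @export
write_posterior <- function(samples, outdir, input_path = NULL) {
  if (samples$n_retained < 1) stop("empty posterior sample set")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(lapply(samples$theta,
                                     function(x) format(x, digits = 17))),
                   file.path(outdir, "theta.csv"), row.names = FALSE,
                   quote = FALSE)
  idx <- which(samples$spikes > 0, arr.ind = TRUE)
  data.table::fwrite(data.table::data.table(
    iteration = idx[, 1], step = idx[, 2],
    count = samples$spikes[idx]), file.path(outdir, "spikes.csv"))
  sm <- summarize_samples(samples, bin_width = 1)
  data.table::fwrite(data.table::data.table(
    step = seq_along(sm$mean_spikes), mean_spikes = sm$mean_spikes,
    sd_spikes = sm$sd_spikes, burst_prob = sm$burst_prob,
    mean_baseline = sm$mean_baseline, sd_baseline = sm$sd_baseline),
    file.path(outdir, "summary.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pgbar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(samples$config),
    dt = samples$dt, n_retained = samples$n_retained)
  if (!is.null(input_path))
    manifest$input <- list(path = input_path,
                           md5 = unname(tools::md5sum(input_path)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Re-read posterior theta draws
#'
#' @param outdir directory written by [write_posterior()].
#' @return data.frame of theta draws.
#' @export
read_posterior_theta <- function(outdir) {
  utils::read.csv(file.path(outdir, "theta.csv"))
}

#' Densify a sparse spike raster
#'
#' @param spikes_csv path of a sparse `spikes.csv` written by
#'   [write_posterior()].
#' @param n_iterations,t_steps dense dimensions.
#' @return Integer matrix (iterations x steps).
#' @export
densify_spikes <- function(spikes_csv, n_iterations, t_steps) {
  sp <- data.table::fread(spikes_csv)
  m <- matrix(0L, n_iterations, t_steps)
  if (nrow(sp) > 0)
    m[cbind(sp$iteration, sp$step)] <- as.integer(sp$count)
  m
}

#' Path of the command-line interface script
#'
#' The CLI lives in `inst/cli/pgbar.R`; run it as
#' `Rscript $(Rscript -e 'cat(pgbar::cli_path())') fit trace.csv --out dir`.
#' Subcommands: `fit`, `simulate`, `metrics`, `bench`.
#'
#' @return Path of the installed CLI script.
#' @export
cli_path <- function() {
  system.file("cli", "pgbar.R", package = "pgbar", mustWork = TRUE)
}
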