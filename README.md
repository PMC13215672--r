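# pgbar

Bayesian spike inference from calcium-fluorescence time series by particle
Gibbs sampling on a bursting autoregressive state-space model.

## Who this is for

Calcium imaging reports spikes indirectly: each action potential produces a
fluorescence transient (finite rise, exponential decay) riding on a drifting
baseline plus noise. Deconvolution tools that return a single best spike
train give no statistical confidence for any inferred spike, and most
require externally calibrated kernel parameters. `pgbar` is for
experimenters and analysts who need *posterior distributions* — over spike
times, burst epochs, baseline drift, and every model parameter — from a
single normalized fluorescence (dF/F) trace, including high-rate recordings
(kHz line scans with fast indicators) where inter-spike intervals of a few
milliseconds matter.

## The model and sampler

Observation: `F_t = c_t + b_t + eta_t`, `eta_t ~ N(0, sigma^2)`.

* **Spiking** — a hidden two-state regime `q_t` switches between a baseline
  rate `r0` and a burst rate `r1` (per-step switching probabilities
  `w01*dt`, `w10*dt`); spike counts are `s_t ~ Pois(r_{q_t} dt)`.
* **Calcium** — a deterministic AR(2) response
  `c_t = gamma1 c_{t-1} + gamma2 c_{t-2} + A s_t`, parameterized by peak
  amplitude `A_max` (dF/F), rise time `tau_r` and decay time `tau_d`
  (seconds), with exact maps both ways (`kinetics_to_ar()`,
  `ar_to_kinetics()`).
* **Baseline** — a Gaussian random walk with variance rate `sigma_b^2`.
* **Inference** — a Gibbs sampler alternating (1) a conditional sequential
  Monte Carlo sweep with ancestor sampling over the latent trajectory,
  using the analytically derived optimal proposal (baseline integrated in
  closed form), and (2) conjugate gamma / inverse-gamma draws for rates and
  variances plus Metropolis steps for the kernel parameters. Priors:
  truncated-normal for `A_max, c0, tau_r, tau_d`; gamma for rates;
  inverse-gamma for variances.

Sampler correctness is tested three ways: exhaustive enumeration of the
latent posterior on short traces, a Geweke successive-conditional test
(which also detects a deliberately broken weight formula), and
Kolmogorov–Smirnov checks of every conjugate update. See the methods
vignette (`vignettes/pgbar-methods.Rmd`) for the model, numerical choices
and design rationale.

## Worked example

Simulate a 3 kHz trace with two spikes 10 ms apart at SNR 3.4 (a
fast-indicator setting: rise 3.7 ms, decay 40 ms, unit dF/F peak), then
sample the posterior:

```r
library(pgbar)
theta <- model_parameters(r0 = 0.1, r1 = 20, w01 = 0.5, w10 = 2,
                          a_max = 1, tau_r = 0.0037, tau_d = 0.040, c0 = 0,
                          sigma2 = (1 / 3.4)^2, sigma2_b = 0.005)
sim <- simulate_stimulus_trace(c(0.200, 0.210), theta, t_steps = 1800,
                               dt = 1 / 3000, seed = 42)
cfg <- sampler_config(n_iterations = 1500, burn_in = 500, n_particles = 100,
                      seed = 1, deterministic_start = TRUE)
fit <- run_sampler(sim$trace, fast_indicator_priors(), cfg)
fit
#> Posterior samples: 1000 retained draws, T = 1800 steps, dt = 0.000333333 s
#>   mean total spikes 2.00; MH acceptance: a_max 0.33, tau_r 0.28, tau_d 0.31, c0 0.43

isi <- isi_posterior(fit, window = c(0.175, 0.235))
isi$two_spike_fraction   # fraction of posterior draws with exactly 2 spikes
#> [1] 1
isi$mode_ms              # posterior mode of the inter-spike interval (ms)
#> [1] 10.5
```

Every retained draw contains exactly two spikes in the stimulus window, and
the inter-spike-interval posterior peaks in the 3 ms histogram bin holding
the true 10 ms interval — the sampler resolves the spike pair and reports
its confidence, not just a point estimate. `summarize_samples()` gives
per-step spike probabilities, burst probabilities and baseline bands;
`filtered_correlation()`, `error_and_bias()`, `detection_metrics()` and
`correlation_vs_binsize()` score inferred trains against ground truth.

## Command line

```sh
CLI=$(Rscript -e 'cat(pgbar::cli_path())')
Rscript $CLI simulate --two-spike --isi 5 --snr 2.4 --out simdir
Rscript $CLI fit simdir/trace.csv --config inst/extdata/default_config.json --out fitdir
Rscript $CLI metrics --samples fitdir --truth simdir/truth.csv
Rscript $CLI bench                 # sweep runtime grid (informational)
```

Configuration is one JSON file with a `priors` section (science) and a
`sampler` section (engineering); `inst/extdata/default_config.json`
documents every field.

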