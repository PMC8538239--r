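# Shared fixtures for the test suite.

# Run the full trace-level pipeline on one simulated recording and return
# per-method MAE and bias against the window-averaged ground truth.
run_sim_stats <- function(cfg, methods = c("EA", "PCA", "ICA")) {
  rgb <- simulate_rgb(cfg)
  trj <- simulate_trajectories(cfg)
  res <- suppressWarnings(
    run_pipeline(list(traces = rgb$traces, traj = trj$traj), method = methods)
  )
  out <- sapply(split(res$hr, res$hr$method), function(d) {
    a <- agreement(d, windowed_reference(rgb$truth, d$time, res$window_s))
    c(mae = a$mae, bias = a$bias)
  })
  out
}

# Seed-averaged per-method MAE/bias for a scenario preset (or any sim_config
# overrides), cached so several test blocks can share one computation.
.scenario_cache <- new.env(parent = emptyenv())

scenario_stats <- function(name, seeds = 1:20, duration = 60) {
  key <- paste(name, paste(range(seeds), collapse = "-"), duration)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  per_seed <- lapply(seeds, function(sd) {
    run_sim_stats(scenario(name, duration = duration, seed = sd))
  })
  mae <- rowMeans(sapply(per_seed, function(m) m["mae", ]))
  bias <- rowMeans(sapply(per_seed, function(m) m["bias", ]))
  out <- list(mae = mae, bias = bias, n_seeds = length(seeds))
  .scenario_cache[[key]] <- out
  out
}

# A unit-variance sinusoid as a signal1d.
tone <- function(freq, fs = 30, duration = 60, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  signal1d(sqrt(2) * sin(2 * pi * freq * t + phase), fs)
}

# Frequency-bin spacing (in bpm) of the padded spectrum used by
# dominant_hr for a signal of n samples at rate fs: estimates are accurate
# to half of this.
bin_bpm <- function(n, fs) {
  nfft <- 2^ceiling(log2(max(n, 120 * fs)))
  60 * fs / nfft
}
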