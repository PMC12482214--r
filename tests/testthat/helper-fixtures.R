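# Shared fixtures, built in code.

# small single-seizure record with the planted pre-ictal gamma effect
tiny_sim <- function(seed = 11, n_channels = 1, pil_minutes = 1,
                     ratio = 3, gain = 4, artifact_rate = 0) {
  geo <- duration_for_ratio(pil_minutes, ratio, 5)
  cfg <- simulation_config(
    n_channels = n_channels, fs = 250, duration = geo$duration,
    seizure_onsets = geo$onset, pil_minutes = pil_minutes,
    preictal_gamma_gain = gain, artifact_rate = artifact_rate,
    seed = seed)
  list(sim = simulate_record(cfg), config = cfg, geo = geo)
}

# toy power spectrum on an explicit grid
toy_spectrum <- function(freqs, power, f_lo = min(freqs),
                         f_hi = max(freqs)) {
  structure(list(freqs = freqs, power = power,
                 band = band_definition("toy", f_lo, f_hi),
                 fs = 2 * max(freqs), df = freqs[2] - freqs[1],
                 ys_avg = mean(power)),
            class = "power_spectrum")
}

# band power of a signal by plain FFT periodogram (independent oracle:
# no package spectral code involved)
oracle_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  p <- Mod(X)^2 / n^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  sum(p[f >= f_lo & f <= f_hi])
}

# random toy dataset for resampling tests
toy_dataset <- function(n1 = 10, n0 = 150, p = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p, mean = 3), n1, p),
             matrix(rnorm(n0 * p), n0, p))
  labeled_dataset(x, c(rep(1L, n1), rep(0L, n0)))
}
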