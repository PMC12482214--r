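#' Configuration for the synthetic EEG generator
#'
#' Describes a 10-20-style multichannel recording with inter-ictal
#' background activity, a pre-ictal period of elevated gamma power with
#' high-frequency-oscillation (HFO) bursts before each seizure onset, an
#' ictal spike-wave discharge, optional artifacts, and 16-bit quantization.
#'
#' @param n_channels Number of channels (default 21).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Record length in seconds.
#' @param seizure_onsets Seizure onset times in seconds; each onset must lie
#'   in `(pil_minutes * 60, duration)` and pre-ictal spans must not overlap.
#' @param pil_minutes Pre-ictal period length in minutes (default 5); the
#'   pre-ictal span before an onset is `[onset - pil_minutes*60, onset)`.
#' @param band_powers Named relative powers of the background band
#'   components (delta, theta, alpha, beta, gamma).
#' @param preictal_gamma_gain Multiplicative gamma-band power gain inside
#'   pre-ictal spans; must exceed 1 so the planted effect is detectable.
#' @param artifact_rate Artifact events per hour (0 disables).
#' @param ictal_seconds Ictal discharge length after each onset.
#' @param quantization_bits Amplitude resolution in bits (default 16).
#' @param seed Integer seed; the record is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_channels = 21, fs = 250, duration = 600,
                              seizure_onsets = numeric(),
                              pil_minutes = 5,
                              band_powers = c(delta = 1, theta = 0.6,
                                              alpha = 0.8, beta = 0.4,
                                              gamma = 0.3),
                              preictal_gamma_gain = 4,
                              artifact_rate = 0,
                              ictal_seconds = 5,
                              quantization_bits = 16,
                              seed = 1L) {
  cfg <- list(n_channels = n_channels, fs = fs, duration = duration,
              seizure_onsets = sort(as.numeric(seizure_onsets)),
              pil_minutes = pil_minutes, band_powers = band_powers,
              preictal_gamma_gain = preictal_gamma_gain,
              artifact_rate = artifact_rate, ictal_seconds = ictal_seconds,
              quantization_bits = quantization_bits, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$duration > 0, cfg$n_channels >= 1,
            cfg$pil_minutes > 0, cfg$quantization_bits >= 2,
            cfg$artifact_rate >= 0)
  if (cfg$preictal_gamma_gain <= 1) {
    stop("preictal_gamma_gain must be > 1 so the planted effect is detectable")
  }
  pil_s <- cfg$pil_minutes * 60
  on <- cfg$seizure_onsets
  if (length(on)) {
    if (any(on <= pil_s) || any(on >= cfg$duration + 1e-9)) {
      stop("every seizure onset must lie in (pil_minutes*60, duration)")
    }
    if (length(on) > 1 && any(diff(on) < pil_s + cfg$ictal_seconds)) {
      stop("pre-ictal spans overlap: onsets are too close together")
    }
  }
  invisible(cfg)
}

#' Record duration giving an exact inter-ictal to pre-ictal ratio
#'
#' For a single seizure whose onset is placed at `duration - ictal_seconds`,
#' returns the duration for which labeled inter-ictal time equals
#' `ratio` times the pre-ictal time.
#'
#' @param pil_minutes Pre-ictal length in minutes.
#' @param ratio Target inter-ictal : pre-ictal ratio (default 15).
#' @param ictal_seconds Ictal discharge length in seconds.
#' @return A list with `duration` and `onset` in seconds.
#' @export
duration_for_ratio <- function(pil_minutes, ratio = 15, ictal_seconds = 5) {
  pil_s <- pil_minutes * 60
  onset <- pil_s * (1 + ratio)
  list(duration = onset + ictal_seconds, onset = onset)
}

## band-limited Gaussian noise via FFT masking, unit variance
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- freq_axis(n, fs)
  X[!(f >= f_lo & f <= f_hi)] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

## 1/f-colored noise with a steep roll-off above `knee` Hz, unit variance
colored_noise <- function(n, fs, knee = 25) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- freq_axis(n, fs)
  shape <- 1 / sqrt(pmax(f, 0.5))
  hi <- f > knee
  shape[hi] <- shape[hi] * (knee / f[hi])^2
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

## symmetric frequency axis |f| for an n-point FFT
freq_axis <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

#' Simulate an annotated multichannel EEG record
#'
#' The inter-ictal background of every channel is the sum of 1/f-colored
#' noise and five band-limited components (delta, theta, alpha, beta, gamma
#' restricted to 30-45 Hz) each carrying a shared sinusoid with a random
#' per-channel phase. Inside each pre-ictal span the gamma component's power
#' is multiplied by `preictal_gamma_gain` and short HFO-like tone bursts
#' (75-95 Hz, ~0.15 s) are injected; after each onset a large 3.5 Hz
#' spike-wave discharge runs for `ictal_seconds`. Samples are quantized to
#' `quantization_bits`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `record` (an [eeg_record()]) and `truth`
#'   (per-state spans plus the annotation table).
#' @export
simulate_record <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  nch <- config$n_channels
  pil_s <- config$pil_minutes * 60
  tt <- seq_len(n) / fs
  onsets <- config$seizure_onsets

  sub <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
              beta = c(13, 30), gamma = c(30, 45))
  centers <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 40)
  amp <- sqrt(config$band_powers)

  pil_mask <- rep(FALSE, n)
  ictal_mask <- rep(FALSE, n)
  for (on in onsets) {
    i0 <- max(1L, floor((on - pil_s) * fs) + 1L)
    i1 <- max(i0, floor(on * fs))
    pil_mask[i0:i1] <- TRUE
    j1 <- min(n, floor((on + config$ictal_seconds) * fs))
    if (i1 < j1) ictal_mask[(i1 + 1L):j1] <- TRUE
  }
  gain_a <- sqrt(config$preictal_gamma_gain)

  data <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    x <- 0.6 * colored_noise(n, fs)
    for (b in names(sub)) {
      comp <- bandlimited_noise(n, fs, sub[[b]][1], sub[[b]][2]) +
        0.5 * sin(2 * pi * centers[[b]] * tt + stats::runif(1, 0, 2 * pi))
      comp <- amp[[b]] * comp
      if (b == "gamma") comp[pil_mask] <- comp[pil_mask] * gain_a
      x <- x + comp
    }
    ## HFO bursts inside pre-ictal spans, ~1 per second
    for (on in onsets) {
      span0 <- max(0, on - pil_s)
      nb <- stats::rpois(1, (on - span0) * 1.2)
      if (nb > 0) {
        t0s <- stats::runif(nb, span0, on - 0.7)
        f0s <- stats::runif(nb, 78, min(92, fs / 2 - 5))
        for (bi in seq_len(nb)) {
          idx <- which(tt > t0s[bi] & tt < t0s[bi] + 0.6)
          env <- exp(-((tt[idx] - t0s[bi] - 0.3) / 0.1)^2)
          x[idx] <- x[idx] +
            4 * gain_a * amp[["gamma"]] * env *
            cos(2 * pi * f0s[bi] * tt[idx])
        }
      }
    }
    ## ictal spike-wave discharge
    if (any(ictal_mask)) {
      sw <- sin(2 * pi * 3.5 * tt) + 0.5 * sin(2 * pi * 7 * tt) +
        0.33 * sin(2 * pi * 10.5 * tt)
      x[ictal_mask] <- x[ictal_mask] + 6 * sw[ictal_mask]
    }
    data[ch, ] <- 20 * x
  }

  ann <- seizure_annotations(
    onset = onsets,
    offset = pmin(onsets + config$ictal_seconds, config$duration))
  rec <- eeg_record(data, fs,
                    channel_labels = montage_labels(nch),
                    patient_id = sprintf("synthetic-%04d", config$seed),
                    annotations = ann)
  if (config$artifact_rate > 0) {
    rec <- inject_artifacts(rec, config$artifact_rate,
                            seed = config$seed + 7919L)
  }
  rec$data <- quantize_signal(rec$data, config$quantization_bits)
  list(record = rec, truth = ground_truth(config))
}

## standard 10-20 montage names, recycled past 21 channels
montage_labels <- function(nch) {
  std <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
           "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "CZ", "PZ", "A1", "A2")
  if (nch <= length(std)) std[seq_len(nch)] else paste0("CH", seq_len(nch))
}

#' Per-state ground-truth spans for a simulation
#'
#' @param config A [simulation_config()].
#' @return A data frame with columns `start`, `end`, `state` covering
#'   `[0, duration]` without gaps; states are `interictal`, `preictal`,
#'   `ictal`.
#' @export
ground_truth <- function(config) {
  pil_s <- config$pil_minutes * 60
  dur <- config$duration
  spans <- data.frame(start = numeric(), end = numeric(),
                      state = character())
  cursor <- 0
  for (on in config$seizure_onsets) {
    p0 <- max(0, on - pil_s)
    if (p0 > cursor) {
      spans <- rbind(spans, data.frame(start = cursor, end = p0,
                                       state = "interictal"))
    }
    spans <- rbind(spans, data.frame(start = p0, end = on,
                                     state = "preictal"))
    i1 <- min(dur, on + config$ictal_seconds)
    if (i1 > on) {
      spans <- rbind(spans, data.frame(start = on, end = i1,
                                       state = "ictal"))
    }
    cursor <- i1
  }
  if (cursor < dur) {
    spans <- rbind(spans, data.frame(start = cursor, end = dur,
                                     state = "interictal"))
  }
  spans
}

#' Quantize a signal to an integer amplitude grid
#'
#' Rounds each channel to a `2^bits`-level grid spanning its own range,
#' emulating fixed-resolution acquisition hardware.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param bits Resolution in bits.
#' @return Quantized object of the same shape.
#' @export
quantize_signal <- function(x, bits = 16) {
  q1 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) return(v)
    step <- (hi - lo) / (2^bits - 1)
    round((v - lo) / step) * step + lo
  }
  if (is.matrix(x)) t(apply(x, 1, q1)) else q1(x)
}

#' Inject physiological artifacts into a record
#'
#' Adds artifact waveforms at Poisson-distributed times: high-amplitude
#' blink-like biphasic transients (< 2 Hz, ~0.5 s) and broadband muscle
#' bursts (20 Hz to high gamma, ~0.3 s), each on a random subset of
#' channels. The artifact count and placement are reproducible from `seed`.
#'
#' @param record An [eeg_record()].
#' @param rate Events per hour; `0` returns the record unchanged.
#' @param seed Integer seed.
#' @return A copy of the record with artifacts added; the artifact log is
#'   attached as attribute `"artifacts"`.
#' @export
inject_artifacts <- function(record, rate, seed = 1L) {
  stopifnot(rate >= 0)
  if (rate == 0) return(record)
  set.seed(as.integer(seed))
  fs <- record$fs
  n <- ncol(record$data)
  nch <- nrow(record$data)
  dur <- n / fs
  count <- stats::rpois(1, rate * dur / 3600)
  log <- data.frame(time = numeric(), type = character())
  if (count > 0) {
    times <- sort(stats::runif(count, 0.5, max(0.6, dur - 1)))
    types <- sample(c("blink", "muscle"), count, replace = TRUE)
    tt <- seq_len(n) / fs
    for (k in seq_len(count)) {
      chs <- sample(nch, max(1L, min(nch, sample(3L, 1))))
      if (types[k] == "blink") {
        idx <- which(tt > times[k] & tt < times[k] + 0.5)
        wave <- 180 * sin(2 * pi * 1.5 * (tt[idx] - times[k])) *
          sin(pi * (tt[idx] - times[k]) / 0.5)^2
      } else {
        idx <- which(tt > times[k] & tt < times[k] + 0.3)
        wave <- 60 * bandlimited_noise(length(idx), fs, 20,
                                       min(100, fs / 2 - 1)) *
          sin(pi * (tt[idx] - times[k]) / 0.3)^2
      }
      for (ch in chs) {
        record$data[ch, idx] <- record$data[ch, idx] + wave
      }
    }
    log <- data.frame(time = times, type = types)
  }
  attr(record, "artifacts") <- log
  record
}
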