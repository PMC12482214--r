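#' Configuration for multiresolution adaptive filtering
#'
#' @param wavelet Mother wavelet for the denoising stage (default `"db4"`).
#' @param levels Decomposition depth; `NULL` selects
#'   `floor(log2(window_samples)) - 2` per segment.
#' @param taps Number of adaptive-filter taps `s` (default 8).
#' @param mu Normalized-LMS step size (default 0.01).
#' @return An `mraf_config` list.
#' @export
mraf_config <- function(wavelet = "db4", levels = NULL, taps = 8L,
                        mu = 0.01) {
  stopifnot(taps >= 1L, mu > 0)
  if (!is.null(levels)) stopifnot(levels >= 1L)
  structure(list(wavelet = wavelet, levels = levels, taps = as.integer(taps),
                 mu = mu), class = "mraf_config")
}

#' Segment a record into non-overlapping analysis windows
#'
#' Segments are contiguous with `window_samples = round(window_s * fs)`;
#' a trailing partial segment is discarded.
#'
#' @param record An [eeg_record()].
#' @param window_s Window length in seconds (default 4).
#' @return A `segment_grid` list with `window_s`, `window_samples`, `k`
#'   (number of segments), `start_times` and `fs`.
#' @export
segment_eeg <- function(record, window_s = 4) {
  ws <- round(window_s * record$fs)
  if (ws < 2) stop("window_s * fs must be at least 2")
  k <- ncol(record$data) %/% ws
  if (k < 1) stop("record is shorter than one window")
  structure(list(window_s = window_s, window_samples = as.integer(ws),
                 k = as.integer(k),
                 start_times = (seq_len(k) - 1L) * ws / record$fs,
                 fs = record$fs),
            class = "segment_grid")
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("<segment_grid> %d segments of %g s (%d samples) @ %g Hz\n",
              x$k, x$window_s, x$window_samples, x$fs))
  invisible(x)
}

## exact FFT band-limitation (zero all bins outside [f_lo, f_hi])
band_limit <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- freq_axis(n, fs)
  X[!(f >= f_lo & f <= f_hi)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Multiresolution adaptive filter for one band
#'
#' The segment is wavelet soft-threshold denoised, the denoised signal is
#' band-limited to `[f_lo, f_hi]` to form the filter input, and a
#' normalized-LMS FIR filter with `taps` weights adapts that input toward
#' the denoised signal. The output is the filter's causal response, so its
#' spectrum stays inside the band while the adaptive gain tracks the
#' segment.
#'
#' @param segment Numeric vector (one channel, one analysis window).
#' @param fs Sampling rate in Hz.
#' @param band A [band_definition()]; must lie within the Nyquist range.
#' @param config An [mraf_config()].
#' @return Filtered numeric vector, same length as `segment`.
#' @export
mraf_filter <- function(segment, fs, band, config = mraf_config()) {
  if (band$f_hi > fs / 2 + 1e-9) stop("band extends beyond the Nyquist frequency")
  den <- soft_threshold_denoise(segment, config)
  mraf_band_stage(den, fs, band, config)
}

## band stage applied to an already-denoised segment
mraf_band_stage <- function(den, fs, band, config) {
  if (band$name == "fb") return(den)
  xb <- band_limit(den, fs, band$f_lo, band$f_hi)
  nlms_filter_cpp(xb, den, config$taps, config$mu, 1e-8)$y
}

#' Band-filtered segment tensor
#'
#' Applies [mraf_filter()] to every band, channel and segment of a record.
#' The full band (`fb`) is the pass-through of the denoised signal.
#'
#' @param record An [eeg_record()].
#' @param grid A [segment_grid()] from [segment_eeg()].
#' @param bands List of [band_definition()]s (default [default_bands()]).
#' @param config An [mraf_config()].
#' @param channels Integer vector of channels to process (default all).
#' @return A 4-d array `band x channel x segment x window_samples` with
#'   band dimnames, class `band_filtered_segments`.
#' @export
decompose_bands <- function(record, grid, bands = NULL,
                            config = mraf_config(), channels = NULL) {
  if (is.null(bands)) bands <- default_bands(record$fs)
  if (is.null(channels)) channels <- seq_len(nrow(record$data))
  ws <- grid$window_samples
  out <- array(NA_real_,
               dim = c(length(bands), length(channels), grid$k, ws),
               dimnames = list(band_names(bands), NULL, NULL, NULL))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    for (k in seq_len(grid$k)) {
      seg <- record$data[ch, ((k - 1L) * ws + 1L):(k * ws)]
      den <- soft_threshold_denoise(seg, config)
      for (bi in seq_along(bands)) {
        out[bi, ci, k, ] <- mraf_band_stage(den, record$fs, bands[[bi]],
                                            config)
      }
    }
  }
  structure(out, class = c("band_filtered_segments", "array"),
            bands = bands, fs = record$fs, window_s = grid$window_s)
}
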