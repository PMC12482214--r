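#' Per-band periodogram of one segment
#'
#' Computes a one-sided periodogram of the demeaned segment, zero-padded to
#' the smallest power-of-two FFT length giving a bin spacing of at most
#' `df_max` Hz, and restricts it to the band's bins. The scaling satisfies
#' Parseval's relation: summing `power * df` over the full frequency axis
#' recovers the segment variance.
#'
#' @param segment Numeric vector, length >= 16.
#' @param fs Sampling rate in Hz.
#' @param band A [band_definition()].
#' @param df_max Maximum frequency-bin spacing in Hz (default 0.1).
#' @return A `power_spectrum` list: `freqs`, `power`, `band`, `fs`, `df`,
#'   and `ys_avg` (arithmetic mean of in-band power).
#' @export
compute_psd <- function(segment, fs, band, df_max = 0.1) {
  n <- length(segment)
  if (n < 16) stop("segment must contain at least 16 samples")
  nfft <- 2^ceiling(log2(max(n, fs / df_max)))
  x <- segment - mean(segment)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- nfft %/% 2L
  p <- (Mod(X[seq_len(half + 1L)])^2) / (fs * n)
  p[2:half] <- 2 * p[2:half]
  freqs <- (0:half) * fs / nfft
  df <- fs / nfft
  sel <- freqs >= band$f_lo - 1e-9 & freqs <= band$f_hi + 1e-9
  if (!any(sel)) stop("no frequency bins fall inside the band")
  structure(list(freqs = freqs[sel], power = p[sel], band = band, fs = fs,
                 df = df, ys_avg = mean(p[sel])),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s band, %d bins (%.3f Hz spacing), mean power %.3g\n",
              x$band$name, length(x$freqs), x$df, x$ys_avg))
  invisible(x)
}

#' Spectral verge of a power spectrum
#'
#' The highest frequency whose power strictly exceeds the band's mean
#' power. For a degenerate (flat) spectrum with no strictly-above-mean bin
#' the arg-max-power frequency (first such bin) is returned instead.
#'
#' @param ps A [compute_psd()] result.
#' @return Frequency in Hz.
#' @export
spectral_verge <- function(ps) {
  above <- ps$power > ps$ys_avg
  if (any(above)) max(ps$freqs[above]) else ps$freqs[which.max(ps$power)]
}

#' Objective function for critical-spectral-verge refinement
#'
#' Returns the vectorized fitness `f(m) = m` when the power of the bin
#' nearest `m` strictly exceeds the band's mean power, and a large negative
#' penalty otherwise, over the band's frequency range. Maximising it over
#' the band recovers the highest above-mean frequency.
#'
#' @param ps A [compute_psd()] result.
#' @param penalty Value returned at below-mean frequencies.
#' @return A function mapping Hz to fitness, with attributes `bounds`.
#' @export
csv_objective <- function(ps, penalty = -1e6) {
  freqs <- ps$freqs
  power <- ps$power
  avg <- ps$ys_avg
  f0 <- freqs[1]
  df <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  fn <- function(m) {
    idx <- pmin(pmax(round((m - f0) / df) + 1, 1), length(freqs))
    ifelse(power[idx] > avg, m, penalty)
  }
  attr(fn, "bounds") <- c(min(freqs), max(freqs))
  fn
}
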