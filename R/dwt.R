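## Orthogonal DWT with symmetric boundary extension.
##
## Filter-bank convolution layout matches the common symmetric-extension
## convention: the forward transform extends the signal by L-1 samples on
## each side, convolves with the decomposition filters and keeps every
## second sample; the redundant boundary coefficients make the transform
## exactly invertible.

wt_filters <- function(wavelet = "db4") {
  h <- switch(wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114,
            0.030841381835986965, 0.032883011666982945,
            -0.010597401784997278),
    stop("unsupported wavelet: ", wavelet)
  )
  L <- length(h)
  rec_lo <- h
  rec_hi <- (-1)^(seq_len(L) - 1) * rev(h)
  list(dec_lo = rev(rec_lo), dec_hi = rev(rec_hi),
       rec_lo = rec_lo, rec_hi = rec_hi, length = L)
}

conv_full <- function(x, f) {
  n <- length(x) + length(f) - 1L
  Re(stats::fft(stats::fft(c(x, rep(0, n - length(x)))) *
                stats::fft(c(f, rep(0, n - length(f)))), inverse = TRUE)) / n
}

dwt_step <- function(x, filt) {
  L <- filt$length
  n <- length(x)
  p <- L - 1L
  ext <- c(rev(x[seq_len(min(p, n))]), x, rev(x[(n - min(p, n) + 1L):n]))
  if (min(p, n) < p) { # very short signals: repeat extension
    while (length(ext) < n + 2L * p) ext <- c(ext[1], ext, ext[length(ext)])
  }
  nc <- (n + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = nc)
  list(ca = conv_full(ext, filt$dec_lo)[idx],
       cd = conv_full(ext, filt$dec_hi)[idx])
}

idwt_step <- function(ca, cd, filt, out_len) {
  L <- filt$length
  up <- function(c) { u <- numeric(2L * length(c)); u[seq(1, by = 2, length.out = length(c))] <- c; u }
  rec <- conv_full(up(ca), filt$rec_lo) + conv_full(up(cd), filt$rec_hi)
  full <- rec[(L - 1L):(L - 2L + 2L * length(ca) - L + 2L)]
  full[seq_len(out_len)]
}

#' Multi-level discrete wavelet decomposition
#'
#' @param x Numeric vector.
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`.
#' @param levels Decomposition depth (>= 1).
#' @return A `wavedec` list: `approx` (level-`levels` approximation),
#'   `details` (list, level 1 = finest), `lengths` (input length per
#'   level, for reconstruction), `wavelet`.
#' @export
wavedec <- function(x, wavelet = "db4", levels = 1L) {
  stopifnot(levels >= 1L, length(x) >= 2L)
  filt <- wt_filters(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- as.numeric(x)
  for (l in seq_len(levels)) {
    lengths[l] <- length(a)
    s <- dwt_step(a, filt)
    details[[l]] <- s$cd
    a <- s$ca
  }
  structure(list(approx = a, details = details, lengths = lengths,
                 wavelet = wavelet), class = "wavedec")
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' @param wd A [wavedec()] object.
#' @return Numeric vector of the original length.
#' @export
waverec <- function(wd) {
  filt <- wt_filters(wd$wavelet)
  a <- wd$approx
  for (l in rev(seq_along(wd$details))) {
    a <- idwt_step(a, wd$details[[l]], filt, wd$lengths[l])
  }
  a
}

#' Universal soft threshold for one detail level
#'
#' The level threshold is `sigma_l * sqrt(2 * log(P))` (natural
#' logarithm), where `P` is the number of samples in the analysed segment
#' and `sigma_l` defaults to the standard deviation of the supplied
#' coefficients. The denoising pipeline passes a robust noise estimate
#' for `sigma` instead, so that signal-bearing levels are not shrunk in
#' proportion to their own energy.
#'
#' @param detail_coeffs Numeric vector of detail coefficients.
#' @param P Segment sample count; must be at least 2.
#' @param sigma Optional noise standard deviation overriding the
#'   coefficient standard deviation.
#' @return The threshold value (scalar, >= 0).
#' @export
universal_threshold <- function(detail_coeffs, P, sigma = NULL) {
  if (!is.numeric(P) || length(P) != 1L || P < 2) stop("P must be >= 2")
  if (is.null(sigma)) {
    sigma <- if (length(detail_coeffs) >= 2L) stats::sd(detail_coeffs) else 0
  }
  if (!is.finite(sigma)) sigma <- 0
  sigma * sqrt(2 * log(P))
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet soft-threshold denoising
#'
#' Decomposes the signal, shrinks every detail level by the soft rule
#' `sign(c) * max(|c| - Z_l, 0)` with the level's [universal_threshold()],
#' and reconstructs. Output length equals input length.
#'
#' @param signal Numeric vector, all finite, length >= `2^levels`.
#' @param config An [mraf_config()].
#' @return Denoised numeric vector.
#' @export
soft_threshold_denoise <- function(signal, config = mraf_config()) {
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  levels <- config$levels
  if (is.null(levels)) levels <- default_dwt_levels(length(signal))
  if (length(signal) < 2^levels) stop("signal shorter than 2^levels")
  wd <- wavedec(signal, config$wavelet, levels)
  P <- length(signal)
  ## noise scale from the (noise-dominated) finest detail level, MAD-based
  sigma <- stats::mad(wd$details[[1L]], constant = 1.4826)
  wd$details <- lapply(wd$details, function(d) {
    soft_threshold(d, universal_threshold(d, P, sigma = sigma))
  })
  waverec(wd)
}

default_dwt_levels <- function(n) max(1L, floor(log2(n)) - 2L)
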