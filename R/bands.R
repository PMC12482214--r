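#' Define an EEG frequency band
#'
#' @param name Band name (e.g. "alpha").
#' @param f_lo,f_hi Band edges in Hz; requires `0 <= f_lo < f_hi`.
#' @return A `band_definition` list with elements `name`, `f_lo`, `f_hi`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(f_lo), is.numeric(f_hi), length(f_lo) == 1L,
            length(f_hi) == 1L)
  if (!(f_lo >= 0 && f_lo < f_hi)) {
    stop("band edges must satisfy 0 <= f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Standard EEG band set
#'
#' The canonical clinical bands, in the order the feature map stacks them:
#' alpha 8-13 Hz, beta 13-30 Hz, gamma 30-100 Hz (capped at Nyquist),
#' theta 4-8 Hz, delta 0.5-4 Hz, and the full band 0.5 Hz to Nyquist.
#' With `gamma_split = TRUE` the gamma band is replaced by gamma1 30-70 Hz
#' and gamma2 70-128 Hz (capped at Nyquist), giving the 7-row variant.
#'
#' @param fs Sampling rate in Hz (sets the Nyquist cap).
#' @param gamma_split Split gamma into gamma1/gamma2?
#' @return A list of [band_definition()] objects.
#' @export
default_bands <- function(fs = 250, gamma_split = FALSE) {
  nyq <- fs / 2
  cap <- function(hi) min(hi, nyq)
  gamma <- if (gamma_split) {
    list(band_definition("gamma1", 30, cap(70)),
         band_definition("gamma2", min(70, nyq - 1), cap(128)))
  } else {
    list(band_definition("gamma", 30, cap(100)))
  }
  c(list(band_definition("alpha", 8, 13),
         band_definition("beta", 13, 30)),
    gamma,
    list(band_definition("theta", 4, 8),
         band_definition("delta", 0.5, 4),
         band_definition("fb", 0.5, nyq)))
}

band_names <- function(bands) vapply(bands, `[[`, character(1), "name")

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %.1f-%.1f Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}
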