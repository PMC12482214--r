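#' Critical-spectral-verge feature map
#'
#' For every band, segment and channel of a band-filtered tensor: compute
#' the band periodogram, seed the search with the [spectral_verge()], and
#' refine it by flower-pollination optimization of the [csv_objective()]
#' within the band's own frequency range (the full band searches up to
#' Nyquist). Rows follow the band order of the input tensor.
#'
#' @param filtered A `band_filtered_segments` tensor from
#'   [decompose_bands()].
#' @param fpm An [fpm_config()]; its `bounds` are overridden per band and
#'   its `seed` (combined with the band/segment/channel index) makes the
#'   map reproducible.
#' @param refine Use the optimizer (`TRUE`, default) or fall back to the
#'   raw spectral verge.
#' @return A `csv_feature_map` array `band x segment x channel` of
#'   frequencies in Hz.
#' @export
build_feature_map <- function(filtered, fpm = fpm_config(), refine = TRUE) {
  bands <- attr(filtered, "bands")
  fs <- attr(filtered, "fs")
  d <- dim(filtered)
  nb <- d[1]; nch <- d[2]; k <- d[3]
  map <- array(NA_real_, dim = c(nb, k, nch),
               dimnames = list(band_names(bands), NULL, NULL))
  base_seed <- if (is.null(fpm$seed)) 0L else as.integer(fpm$seed)
  for (bi in seq_len(nb)) {
    bnd <- bands[[bi]]
    for (ci in seq_len(nch)) {
      for (ki in seq_len(k)) {
        ps <- compute_psd(filtered[bi, ci, ki, ], fs, bnd)
        sv <- spectral_verge(ps)
        if (refine) {
          cfg <- fpm
          cfg$bounds <- c(min(ps$freqs), max(ps$freqs))
          cfg$seed <- (base_seed + 97L * bi + 1009L * ci + 9173L * ki) %%
            2147483647L
          res <- fpm_optimize(csv_objective(ps), sv, cfg)
          map[bi, ki, ci] <- res$csv
        } else {
          map[bi, ki, ci] <- sv
        }
      }
    }
  }
  structure(map, class = c("csv_feature_map", "array"), bands = bands,
            fs = fs, window_s = attr(filtered, "window_s"))
}

#' Export a feature map in long format
#'
#' @param map A [build_feature_map()] result.
#' @param path Optional CSV path; when `NULL` the data frame is returned
#'   only.
#' @return A data frame with columns `channel`, `band`, `segment`,
#'   `csv_hz`.
#' @export
feature_map_long <- function(map, path = NULL) {
  d <- dim(map)
  df <- data.frame(
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    band = rep(rownames(map), times = d[2] * d[3]),
    segment = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    csv_hz = as.vector(map))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
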