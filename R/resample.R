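#' Construct a labeled window dataset
#'
#' @param x Numeric feature matrix, one row per window.
#' @param y Integer labels, 1 = pre-ictal (minority), 0 = inter-ictal.
#' @param patient Optional patient identifier per window.
#' @param id Optional unique window identifier (defaults to row index).
#' @return A `labeled_dataset` list.
#' @export
labeled_dataset <- function(x, y, patient = NULL, id = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(patient)) patient <- rep("p1", length(y))
  if (is.null(id)) id <- seq_along(y)
  structure(list(x = x, y = as.integer(y), patient = patient, id = id),
            class = "labeled_dataset")
}

check_both_classes <- function(data) {
  if (length(unique(data$y)) < 2L) {
    stop("resampling requires both classes to be present")
  }
}

resample_assemble <- function(data, keep_idx, synth_x = NULL,
                              synth_y = integer()) {
  x <- data$x[keep_idx, , drop = FALSE]
  y <- data$y[keep_idx]
  patient <- data$patient[keep_idx]
  id <- data$id[keep_idx]
  if (!is.null(synth_x) && nrow(synth_x)) {
    x <- rbind(x, synth_x)
    y <- c(y, synth_y)
    patient <- c(patient, rep("synthetic", nrow(synth_x)))
    id <- c(id, paste0("synth", seq_len(nrow(synth_x))))
  }
  labeled_dataset(x, y, patient, id)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority rows with replacement until the class counts are
#' equal. Majority rows are never altered.
#'
#' @param data A [labeled_dataset()].
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset`.
#' @export
ros <- function(data, seed = 1L) {
  check_both_classes(data)
  set.seed(as.integer(seed))
  n1 <- sum(data$y == 1L); n0 <- sum(data$y == 0L)
  if (n1 == n0) return(data)
  min_lab <- if (n1 < n0) 1L else 0L
  idx_min <- which(data$y == min_lab)
  extra <- sample(idx_min, abs(n0 - n1), replace = TRUE)
  resample_assemble(data, c(seq_along(data$y), extra))
}

#' Random undersampling of the majority class
#'
#' Subsamples the majority class without replacement down to the minority
#' size.
#'
#' @inheritParams ros
#' @return A balanced `labeled_dataset`.
#' @export
rus <- function(data, seed = 1L) {
  check_both_classes(data)
  set.seed(as.integer(seed))
  n1 <- sum(data$y == 1L); n0 <- sum(data$y == 0L)
  if (n1 == n0) return(data)
  maj_lab <- if (n1 < n0) 0L else 1L
  idx_maj <- which(data$y == maj_lab)
  idx_min <- which(data$y != maj_lab)
  keep_maj <- sample(idx_maj, min(n0, n1))
  resample_assemble(data, sort(c(idx_min, keep_maj)))
}

#' Borderline-SMOTE (variant 1) oversampling
#'
#' Minority points whose `m_neighbors`-neighborhood is majority-dominated
#' (more than half majority, but not entirely majority) are "danger"
#' points. Synthetic samples interpolate danger points toward their
#' `k_neighbors` nearest minority neighbors, `x + u * (x_nn - x)` with
#' `u ~ U(0, 1)`, until the classes balance. With no danger points the
#' interior minority points are interpolated instead; when the minority is
#' too small for the neighborhood (size <= `k_neighbors`) the method falls
#' back to [ros()] with a warning.
#'
#' @param data A [labeled_dataset()].
#' @param k_neighbors Minority neighbors used for interpolation.
#' @param m_neighbors Neighborhood size for the danger test.
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset`.
#' @export
bsmote <- function(data, k_neighbors = 5L, m_neighbors = 10L, seed = 1L) {
  check_both_classes(data)
  set.seed(as.integer(seed))
  n1 <- sum(data$y == 1L); n0 <- sum(data$y == 0L)
  if (n1 == n0) return(data)
  min_lab <- if (n1 < n0) 1L else 0L
  idx_min <- which(data$y == min_lab)
  n_needed <- abs(n0 - n1)
  if (length(idx_min) <= k_neighbors) {
    warning("minority class too small for borderline-SMOTE; falling back to ROS")
    return(ros(data, seed))
  }
  D <- as.matrix(stats::dist(data$x))
  ## danger set from the m-neighborhood over all points
  danger <- logical(length(idx_min))
  for (j in seq_along(idx_min)) {
    i <- idx_min[j]
    nb <- order(D[i, -i])[seq_len(min(m_neighbors, length(data$y) - 1L))]
    nb_idx <- seq_along(data$y)[-i][nb]
    n_maj <- sum(data$y[nb_idx] != min_lab)
    m_eff <- length(nb_idx)
    danger[j] <- n_maj > m_eff / 2 && n_maj < m_eff
  }
  seeds <- if (any(danger)) idx_min[danger] else idx_min
  Dm <- D[, idx_min, drop = FALSE]
  synth <- matrix(NA_real_, n_needed, ncol(data$x))
  picks <- sample(seeds, n_needed, replace = TRUE)
  for (s in seq_len(n_needed)) {
    i <- picks[s]
    ord <- order(Dm[i, ])
    ord <- ord[idx_min[ord] != i]
    nn <- idx_min[ord[sample.int(min(k_neighbors, length(ord)), 1L)]]
    u <- stats::runif(1)
    synth[s, ] <- data$x[i, ] + u * (data$x[nn, ] - data$x[i, ])
  }
  rng <- attr(data, "feature_ranges")
  if (!is.null(rng)) {
    synth <- pmin(pmax(synth, matrix(rng[1, ], n_needed, ncol(synth),
                                     byrow = TRUE)),
                  matrix(rng[2, ], n_needed, ncol(synth), byrow = TRUE))
  }
  resample_assemble(data, seq_along(data$y), synth,
                    rep(min_lab, n_needed))
}

#' Apply a named resampler
#'
#' @param data A [labeled_dataset()].
#' @param method One of `"ros"`, `"rus"`, `"bsmote"`, `"none"`.
#' @param seed Integer seed.
#' @return A `labeled_dataset`.
#' @export
resample_dataset <- function(data, method = c("ros", "rus", "bsmote",
                                              "none"), seed = 1L) {
  method <- match.arg(method)
  switch(method,
         ros = ros(data, seed),
         rus = rus(data, seed),
         bsmote = bsmote(data, seed = seed),
         none = data)
}
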