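#' Extract a CSV feature map from a record
#'
#' Convenience wrapper: segment, band-filter ([decompose_bands()]) and
#' summarise ([build_feature_map()]). With `raw_fb = TRUE` the
#' multiresolution stage is skipped entirely and a single full-band row is
#' computed from raw-segment periodograms (the `no_multiresolution`
#' ablation).
#'
#' @param record An [eeg_record()].
#' @param window_s Segment length in seconds.
#' @param bands Band list (default [default_bands()]).
#' @param mraf An [mraf_config()].
#' @param fpm An [fpm_config()].
#' @param channels Channels to process (default all).
#' @param raw_fb Skip filtering and use raw full-band periodograms only.
#' @return A list with `map` (band x segment x channel array) and `grid`.
#' @export
extract_features <- function(record, window_s = 4, bands = NULL,
                             mraf = mraf_config(), fpm = fpm_config(),
                             channels = NULL, raw_fb = FALSE) {
  grid <- segment_eeg(record, window_s)
  if (is.null(channels)) channels <- seq_len(nrow(record$data))
  if (raw_fb) {
    fb <- band_definition("fb", 0.5, record$fs / 2)
    ws <- grid$window_samples
    map <- array(NA_real_, c(1L, grid$k, length(channels)),
                 dimnames = list("fb", NULL, NULL))
    base_seed <- if (is.null(fpm$seed)) 0L else as.integer(fpm$seed)
    for (ci in seq_along(channels)) {
      for (k in seq_len(grid$k)) {
        seg <- record$data[channels[ci], ((k - 1L) * ws + 1L):(k * ws)]
        ps <- compute_psd(seg, record$fs, fb)
        cfg <- fpm
        cfg$bounds <- c(min(ps$freqs), max(ps$freqs))
        cfg$seed <- (base_seed + 1009L * ci + 9173L * k) %% 2147483647L
        map[1L, k, ci] <- fpm_optimize(csv_objective(ps),
                                       spectral_verge(ps), cfg)$csv
      }
    }
    map <- structure(map, class = c("csv_feature_map", "array"),
                     bands = list(fb), fs = record$fs,
                     window_s = window_s)
    return(list(map = map, grid = grid))
  }
  if (is.null(bands)) bands <- default_bands(record$fs)
  filt <- decompose_bands(record, grid, bands, mraf, channels)
  list(map = build_feature_map(filt, fpm), grid = grid)
}

#' Stack feature-map windows into a CNN input tensor
#'
#' Bands are stacked along the height within each channel block
#' (height = channels x bands); each window covers `width` consecutive
#' segments.
#'
#' @param map A `csv_feature_map` (band x segment x channel).
#' @param windows A [window_spans()] data frame.
#' @return A 4-d array `height x width x 1 x n_windows`.
#' @export
window_tensor <- function(map, windows) {
  d <- dim(map)
  nb <- d[1]; nch <- d[3]
  width <- windows$seg_end[1] - windows$seg_start[1] + 1L
  X <- array(NA_real_, c(nb * nch, width, 1L, nrow(windows)))
  for (w in seq_len(nrow(windows))) {
    segs <- windows$seg_start[w]:windows$seg_end[w]
    for (c in seq_len(nch)) {
      X[((c - 1L) * nb + 1L):(c * nb), , 1L, w] <- map[, segs, c]
    }
  }
  X
}

#' Fit / apply per-row feature standardization
#'
#' Statistics (mean, sd per feature row) are computed on training windows
#' only and applied unchanged elsewhere.
#'
#' @param x 4-d window tensor.
#' @return `fit_scaler`: a scaler list; `apply_scaler`: the scaled tensor.
#' @export
fit_scaler <- function(x) {
  m <- apply(x, 1, mean)
  s <- apply(x, 1, stats::sd)
  s[!is.finite(s) | s < 1e-9] <- 1
  list(mean = m, sd = s)
}

#' @rdname fit_scaler
#' @param scaler A `fit_scaler()` result.
#' @export
apply_scaler <- function(x, scaler) {
  (x - scaler$mean) / scaler$sd
}

flatten_windows <- function(x) {
  d <- dim(x)
  t(matrix(x, prod(d[1:3]), d[4]))
}

unflatten_windows <- function(xm, h, w) {
  array(t(xm), c(h, w, 1L, nrow(xm)))
}

#' Tune the alarm threshold on training windows
#'
#' Picks the threshold maximising Youden's J (sensitivity + specificity
#' - 1) over a grid; ties break toward the higher threshold (fewer false
#' alarms).
#'
#' @param probs Pre-ictal probabilities of training windows.
#' @param labels 0/1 labels.
#' @param grid Candidate thresholds.
#' @return The selected threshold.
#' @export
tune_threshold <- function(probs, labels,
                           grid = seq(0.15, 0.85, by = 0.05)) {
  j <- vapply(grid, function(tau) {
    pred <- as.integer(probs > tau)
    sens <- if (any(labels == 1L)) mean(pred[labels == 1L] == 1L) else 0
    spec <- if (any(labels == 0L)) mean(pred[labels == 0L] == 0L) else 0
    sens + spec - 1
  }, numeric(1))
  grid[max(which(j == max(j)))]
}

#' Train per-band CNN streams with vote fusion
#'
#' One CNN per band row-block (input height = channels); predictions are
#' fused by majority vote over the streams' hard labels (ties toward
#' inter-ictal) or, for the `no_subband_voting` ablation, by averaging
#' the streams' probabilities.
#'
#' @param train,val Lists with `x` (tensor, height = channels x bands) and
#'   `y`.
#' @param nb Number of bands; `nch` channels.
#' @param nch Number of channels.
#' @param config A [cnn_config()].
#' @param fusion `"majority"` or `"average"`.
#' @return A `subband_ensemble` list.
#' @export
train_subband_ensemble <- function(train, val, nb, nch,
                                   config = cnn_config(),
                                   fusion = c("majority", "average")) {
  fusion <- match.arg(fusion)
  streams <- vector("list", nb)
  width <- dim(train$x)[2]
  for (b in seq_len(nb)) {
    rows <- (seq_len(nch) - 1L) * nb + b
    cfg <- config
    cfg$seed <- as.integer(config$seed) + b
    mdl <- build_model(c(nch, width), cfg)
    sub_tr <- list(x = train$x[rows, , , , drop = FALSE], y = train$y)
    sub_va <- list(x = val$x[rows, , , , drop = FALSE], y = val$y)
    streams[[b]] <- train_cnn(mdl, sub_tr, sub_va, cfg)
  }
  structure(list(streams = streams, nb = nb, nch = nch, fusion = fusion),
            class = "subband_ensemble")
}

#' Ensemble prediction with vote or average fusion
#'
#' @param ens A [train_subband_ensemble()] result.
#' @param x Full-height window tensor.
#' @return An `n x 2` probability matrix (columns `IIL`, `PIL`); under
#'   majority fusion the PIL column is the vote fraction.
#' @export
predict_ensemble <- function(ens, x) {
  n <- dim(x)[4]
  p <- matrix(0, n, ens$nb)
  for (b in seq_len(ens$nb)) {
    rows <- (seq_len(ens$nch) - 1L) * ens$nb + b
    p[, b] <- predict_proba(ens$streams[[b]],
                            x[rows, , , , drop = FALSE])[, "PIL"]
  }
  pil <- if (ens$fusion == "majority") {
    rowSums(p > 0.5) / ens$nb
  } else {
    rowMeans(p)
  }
  out <- cbind(IIL = 1 - pil, PIL = pil)
  out
}

simulate_cohort <- function(n_patients, pil_minutes, iil_pil_ratio,
                            gamma_gain, n_channels, fs, artifact_rate,
                            seed, ictal_seconds = 5) {
  geo <- duration_for_ratio(pil_minutes, iil_pil_ratio, ictal_seconds)
  lapply(seq_len(n_patients), function(p) {
    cfg <- simulation_config(
      n_channels = n_channels, fs = fs, duration = geo$duration,
      seizure_onsets = geo$onset, pil_minutes = pil_minutes,
      preictal_gamma_gain = gamma_gain, artifact_rate = artifact_rate,
      ictal_seconds = ictal_seconds,
      seed = (as.integer(seed) + 104729L * p) %% 2147483647L)
    simulate_record(cfg)$record
  })
}

prepare_record_windows <- function(record, pil_minutes, window_s, width,
                                   stride, fpm_seed, raw_fb = FALSE,
                                   mraf = mraf_config(),
                                   fpm = fpm_config()) {
  fpm$seed <- fpm_seed
  feats <- extract_features(record, window_s, mraf = mraf, fpm = fpm,
                            raw_fb = raw_fb)
  win <- label_windows(record, feats$grid, pil_minutes, width, stride)
  keep <- win$label != "excluded"
  X <- window_tensor(feats$map, win)
  list(x = X[, , , keep, drop = FALSE],
       windows = win[keep, , drop = FALSE],
       y = as.integer(win$label[keep] == "PIL"),
       record = record, map = feats$map, grid = feats$grid)
}

#' Scaled-down end-to-end leave-one-seizure-out experiment
#'
#' Simulates a cohort of single-seizure records, extracts CSV feature
#' maps, and evaluates the full pipeline under leave-one-seizure-out
#' cross-validation: per fold the classifier is trained (with feature
#' scaling and resampling fitted on training folds only, and the alarm
#' threshold tuned on training windows), then alarms on the held-out
#' record are scored under SPH/SOP semantics.
#'
#' @param n_patients Number of single-seizure synthetic patients.
#' @param pil_minutes Pre-ictal period in minutes.
#' @param iil_pil_ratio Inter-ictal : pre-ictal duration ratio.
#' @param gamma_gain Planted pre-ictal gamma power gain.
#' @param n_channels Channels per record.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length (s).
#' @param width,stride Classification-window geometry in segments.
#' @param resampler Training-fold resampler name.
#' @param variant `"full"`, `"shallow"`, `"no_multiresolution"` or
#'   `"no_subband_voting"`.
#' @param scoring A [scoring_config()]; its threshold is replaced by the
#'   tuned value per fold.
#' @param cnn A [cnn_config()].
#' @param seed Master seed for every stochastic stage.
#' @return A list with `summary` (pooled SEN, ACC, FPR/h, AUC, counts),
#'   `folds` (per-fold table) and `n_windows`.
#' @export
run_synthetic_experiment <- function(n_patients = 6, pil_minutes = 1.25,
                                     iil_pil_ratio = 15, gamma_gain = 4,
                                     n_channels = 3, fs = 250,
                                     window_s = 4, width = 8L,
                                     stride = 2L,
                                     resampler = "ros",
                                     variant = "full",
                                     scoring = scoring_config(
                                       sph_minutes = 0.25,
                                       sop_minutes = 2.5,
                                       persistence = 2L),
                                     cnn = cnn_config(max_epochs = 40L),
                                     seed = 1L) {
  seed <- as.integer(seed)
  records <- simulate_cohort(n_patients, pil_minutes, iil_pil_ratio,
                             gamma_gain, n_channels, fs,
                             artifact_rate = 0, seed = seed)
  raw_fb <- identical(variant, "no_multiresolution")
  prep <- lapply(seq_along(records), function(i) {
    prepare_record_windows(records[[i]], pil_minutes, window_s, width,
                           stride,
                           fpm_seed = (seed + 31L * i) %% 2147483647L,
                           raw_fb = raw_fb)
  })
  nb <- dim(prep[[1]]$map)[1]
  h <- nb * n_channels
  folds <- loso_folds(seq_along(records))
  fold_rows <- list()
  pool_probs <- numeric(0); pool_labels <- integer(0)
  tot <- list(tp = 0L, fp = 0L, fn = 0L, wtp = 0L, wfp = 0L, wtn = 0L,
              wfn = 0L, hours = 0)
  for (f in seq_along(folds)) {
    te <- folds[[f]]$held_out
    tr_idx <- setdiff(seq_along(records), te)
    Xtr <- do.call(abind4, lapply(prep[tr_idx], `[[`, "x"))
    ytr <- unlist(lapply(prep[tr_idx], `[[`, "y"))
    scaler <- fit_scaler(Xtr)
    Xtr <- apply_scaler(Xtr, scaler)
    ds <- labeled_dataset(flatten_windows(Xtr), ytr,
                          patient = rep(tr_idx, vapply(prep[tr_idx],
                                                       function(p)
                                                         length(p$y),
                                                       integer(1))))
    sp <- split_holdout(ds, 0.8, seed = seed + 11L * f)
    tr_bal <- resample_dataset(sp$train, resampler,
                               seed = seed + 13L * f)
    train_set <- list(x = unflatten_windows(tr_bal$x, h, width),
                      y = tr_bal$y)
    val_set <- list(x = unflatten_windows(sp$test$x, h, width),
                    y = sp$test$y)
    cfg <- cnn
    cfg$seed <- seed + 17L * f
    if (identical(variant, "shallow")) cfg <- shallow_config(cfg)
    ensemble <- variant %in% c("voting", "no_subband_voting")
    if (ensemble) {
      clf <- train_subband_ensemble(
        train_set, val_set, nb, n_channels, cfg,
        fusion = if (identical(variant, "voting")) "majority" else "average")
      prob_fun <- function(x) predict_ensemble(clf, x)
    } else {
      mdl <- build_model(c(h, width), cfg)
      clf <- train_cnn(mdl, train_set, val_set, cfg)
      prob_fun <- function(x) predict_proba(clf, x)
    }
    tau <- tune_threshold(prob_fun(train_set$x)[, "PIL"], train_set$y)
    sc <- scoring
    sc$threshold <- tau
    pt <- prep[[te]]
    Xte <- apply_scaler(pt$x, scaler)
    pte <- prob_fun(Xte)[, "PIL"]
    alarms <- alarms_from_probs(pte, pt$windows, sc)
    ev <- score_alarms(alarms, pt$record$annotations, sc)
    hrs <- interictal_hours(pt$record, alarms, sc, pil_minutes)
    pred <- as.integer(pte > tau)
    wc <- c(wtp = sum(pred == 1 & pt$y == 1),
            wfp = sum(pred == 1 & pt$y == 0),
            wtn = sum(pred == 0 & pt$y == 0),
            wfn = sum(pred == 0 & pt$y == 1))
    tot$tp <- tot$tp + ev$tp; tot$fp <- tot$fp + ev$fp
    tot$fn <- tot$fn + ev$fn; tot$hours <- tot$hours + hrs
    tot$wtp <- tot$wtp + wc["wtp"]; tot$wfp <- tot$wfp + wc["wfp"]
    tot$wtn <- tot$wtn + wc["wtn"]; tot$wfn <- tot$wfn + wc["wfn"]
    pool_probs <- c(pool_probs, pte)
    pool_labels <- c(pool_labels, pt$y)
    fold_rows[[f]] <- data.frame(fold = f, held_out = te, tau = tau,
                                 tp = ev$tp, fp = ev$fp, fn = ev$fn,
                                 interictal_hours = hrs,
                                 n_alarms = length(alarms))
  }
  auc <- auc_score(pool_probs, pool_labels)
  summary <- list(
    sen = tot$tp / (tot$tp + tot$fn),
    fpr_per_hour = tot$fp / tot$hours,
    auc = auc,
    window_acc = unname((tot$wtp + tot$wtn) /
                          (tot$wtp + tot$wtn + tot$wfp + tot$wfn)),
    tp = tot$tp, fp = tot$fp, fn = tot$fn,
    interictal_hours = tot$hours, variant = variant)
  list(summary = summary, folds = do.call(rbind, fold_rows),
       n_windows = length(pool_labels),
       probs = pool_probs, labels = pool_labels)
}

abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[4], integer(1)))
  out <- array(NA_real_, c(d[1:3], n))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[4]
    if (k) out[, , , (at + 1L):(at + k)] <- x
    at <- at + k
  }
  out
}

#' Full-versus-shallow comparison on a holdout classification task
#'
#' Simulates a small cohort once, then for each seed draws a stratified
#' 80/20 split, trains the full and the shallow (2-conv) model, and
#' records their holdout window accuracies.
#'
#' @param seeds Integer seeds for split/training repetitions.
#' @param n_patients,pil_minutes,iil_pil_ratio,gamma_gain,n_channels
#'   Cohort settings (see [run_synthetic_experiment()]).
#' @param width Window width in segments.
#' @param cnn A [cnn_config()].
#' @param seed Seed for simulation and feature extraction.
#' @return A data frame with one row per seed and columns `full_acc`,
#'   `shallow_acc`.
#' @export
compare_full_shallow <- function(seeds = 1:3, n_patients = 2,
                                 pil_minutes = 1.25, iil_pil_ratio = 6,
                                 gamma_gain = 4, n_channels = 3,
                                 width = 8L,
                                 cnn = cnn_config(max_epochs = 40L),
                                 seed = 1L) {
  seed <- as.integer(seed)
  records <- simulate_cohort(n_patients, pil_minutes, iil_pil_ratio,
                             gamma_gain, n_channels, 250, 0, seed)
  prep <- lapply(seq_along(records), function(i) {
    prepare_record_windows(records[[i]], pil_minutes, 4, width, 2L,
                           fpm_seed = (seed + 31L * i) %% 2147483647L)
  })
  nb <- dim(prep[[1]]$map)[1]
  h <- nb * n_channels
  X <- do.call(abind4, lapply(prep, `[[`, "x"))
  y <- unlist(lapply(prep, `[[`, "y"))
  ds <- labeled_dataset(flatten_windows(X), y)
  rows <- lapply(seeds, function(s) {
    sp <- split_holdout(ds, 0.8, seed = s)
    tr_bal <- ros(sp$train, seed = s)
    acc_of <- function(cfg) {
      scaler_x <- unflatten_windows(tr_bal$x, h, width)
      scaler <- fit_scaler(scaler_x)
      tr <- list(x = apply_scaler(scaler_x, scaler), y = tr_bal$y)
      va <- list(x = apply_scaler(unflatten_windows(sp$test$x, h, width),
                                  scaler),
                 y = sp$test$y)
      cfg$seed <- s
      clf <- train_cnn(build_model(c(h, width), cfg), tr, va, cfg)
      mean((predict_proba(clf, va$x)[, "PIL"] > 0.5) == (va$y == 1L))
    }
    data.frame(seed = s, full_acc = acc_of(cnn),
               shallow_acc = acc_of(shallow_config(cnn)))
  })
  do.call(rbind, rows)
}
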