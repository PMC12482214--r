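#' Alarm-scoring configuration
#'
#' SPH (seizure prediction horizon) is the minimum lead time between an
#' alarm and the predicted onset; SOP (seizure occurrence period) is the
#' window after the SPH in which the seizure must begin for the alarm to
#' count as a true positive. Defaults follow the standard 5-minute SPH /
#' 10-minute SOP protocol.
#'
#' @param sph_minutes Seizure prediction horizon in minutes (>= 0).
#' @param sop_minutes Seizure occurrence period in minutes (> 0).
#' @param threshold Alarm probability threshold in (0, 1).
#' @param persistence Consecutive above-threshold windows required before
#'   an alarm fires.
#' @param refractory_s Seconds after an alarm during which further alarms
#'   are suppressed; defaults to the SOP.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(sph_minutes = 5, sop_minutes = 10,
                           threshold = 0.5, persistence = 1L,
                           refractory_s = NULL) {
  stopifnot(sph_minutes >= 0, sop_minutes > 0, threshold > 0,
            threshold < 1, persistence >= 1L)
  if (is.null(refractory_s)) refractory_s <- sop_minutes * 60
  structure(list(sph_s = sph_minutes * 60, sop_s = sop_minutes * 60,
                 threshold = threshold, persistence = as.integer(persistence),
                 refractory_s = refractory_s),
            class = "scoring_config")
}

#' Classification-window spans over a segment grid
#'
#' Windows cover `width` consecutive segments and advance by `stride`
#' segments.
#'
#' @param grid A [segment_eeg()] grid.
#' @param width Window width in segments.
#' @param stride Hop in segments (default `width`, non-overlapping).
#' @return A data frame with columns `window`, `seg_start`, `seg_end`,
#'   `t_start`, `t_end` (seconds).
#' @export
window_spans <- function(grid, width = 1L, stride = width) {
  width <- as.integer(width); stride <- as.integer(stride)
  stopifnot(width >= 1L, stride >= 1L, width <= grid$k)
  starts <- seq(1L, grid$k - width + 1L, by = stride)
  data.frame(window = seq_along(starts),
             seg_start = starts,
             seg_end = starts + width - 1L,
             t_start = (starts - 1L) * grid$window_s,
             t_end = (starts + width - 1L) * grid$window_s)
}

#' Label classification windows from seizure annotations
#'
#' A window is `PIL` when its span intersects a pre-ictal interval
#' `[onset - pil_minutes*60, onset)` (clipped to the record start),
#' `excluded` when it overlaps an ictal interval `[onset, offset)`, and
#' `IIL` otherwise. With no annotations all windows are inter-ictal, with
#' a warning.
#'
#' @param record An [eeg_record()] carrying annotations.
#' @param grid A [segment_eeg()] grid.
#' @param pil_minutes Pre-ictal period length in minutes (default 5).
#' @param width,stride Window geometry in segments (defaults: one segment
#'   per window).
#' @return The [window_spans()] data frame with an added `label` column.
#' @export
label_windows <- function(record, grid, pil_minutes = 5, width = 1L,
                          stride = width) {
  win <- window_spans(grid, width, stride)
  ann <- record$annotations
  win$label <- "IIL"
  if (nrow(ann) == 0L) {
    warning("record has no annotations; all windows labeled inter-ictal")
    return(win)
  }
  pil_s <- pil_minutes * 60
  for (i in seq_len(nrow(ann))) {
    on <- ann$onset[i]; off <- ann$offset[i]
    p0 <- max(0, on - pil_s)
    pil_hit <- win$t_start < on & win$t_end > p0
    win$label[pil_hit] <- "PIL"
    ict_hit <- win$t_start < off & win$t_end > on
    win$label[ict_hit] <- "excluded"
  }
  win
}

#' Turn per-window probabilities into alarm events
#'
#' An alarm fires at the end time of the `persistence`-th consecutive
#' window whose pre-ictal probability exceeds the threshold; for
#' `refractory_s` seconds after an alarm no further alarms are emitted.
#'
#' @param probs Numeric vector of pre-ictal probabilities per window.
#' @param windows A [window_spans()] data frame (same order as `probs`).
#' @param config A [scoring_config()].
#' @return Numeric vector of alarm times (seconds; window end times).
#' @export
alarms_from_probs <- function(probs, windows, config = scoring_config()) {
  stopifnot(length(probs) == nrow(windows), all(probs >= 0 & probs <= 1))
  alarms <- numeric(0)
  consec <- 0L
  last <- -Inf
  for (i in seq_along(probs)) {
    if (probs[i] > config$threshold) consec <- consec + 1L else consec <- 0L
    t <- windows$t_end[i]
    if (consec >= config$persistence && t - last >= config$refractory_s) {
      alarms <- c(alarms, t)
      last <- t
    }
  }
  alarms
}

#' Score alarms against seizure onsets under SPH/SOP semantics
#'
#' An alarm at time `t` is a true positive when some seizure onset falls
#' inside `[t + SPH, t + SPH + SOP]`; onsets are credited to at most one
#' alarm, greedily in time order. Any other alarm - including one whose
#' onset falls inside the SPH - is a false positive, and every seizure
#' with no crediting alarm is a false negative, so `TP + FN` always equals
#' the number of seizures.
#'
#' @param alarms Numeric vector of alarm times in seconds.
#' @param annotations Annotation data frame (see [seizure_annotations()]).
#' @param config A [scoring_config()].
#' @return A list with counts `tp`, `fp`, `fn` and the matched onsets.
#' @export
score_alarms <- function(alarms, annotations, config = scoring_config()) {
  onsets <- sort(annotations$onset)
  matched <- rep(FALSE, length(onsets))
  tp <- 0L; fp <- 0L
  for (t in sort(alarms)) {
    hit <- which(!matched & onsets >= t + config$sph_s &
                   onsets <= t + config$sph_s + config$sop_s)
    if (length(hit)) {
      matched[hit[1]] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!matched),
       matched_onsets = onsets[matched])
}

#' Sensitivity, accuracy and false-prediction rate
#'
#' Sensitivity `TP / (TP + FN)` and the false-prediction rate
#' `FP / inter-ictal hours` use event-level counts; accuracy
#' `(TP + TN) / (TP + FN + TN + FP)` is a window-level quantity and should
#' be fed window-level counts. Undefined ratios (zero denominators) are
#' returned as `NA` with a flag rather than silently as 0.
#'
#' @param tp,fp,fn,tn Counts.
#' @param interictal_hours Hours of inter-ictal recording for the FPR
#'   denominator.
#' @return An `alarm_score` list with `sen`, `acc`, `fpr_per_hour`, the
#'   counts, and `undefined` naming any metric with a zero denominator.
#' @export
compute_metrics <- function(tp, fp, fn, tn = 0, interictal_hours = NA) {
  undefined <- character(0)
  sen <- if ((tp + fn) > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sen"); NA_real_
  }
  total <- tp + fn + tn + fp
  acc <- if (total > 0) (tp + tn) / total else {
    undefined <- c(undefined, "acc"); NA_real_
  }
  fpr <- if (!is.na(interictal_hours) && interictal_hours > 0) {
    fp / interictal_hours
  } else {
    undefined <- c(undefined, "fpr_per_hour"); NA_real_
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 interictal_hours = interictal_hours,
                 sen = sen, acc = acc, fpr_per_hour = fpr,
                 undefined = undefined),
            class = "alarm_score")
}

#' @export
print.alarm_score <- function(x, ...) {
  cat(sprintf("<alarm_score> TP %d FP %d FN %d TN %d | SEN %.3f ACC %.3f FPR %.3f/h\n",
              x$tp, x$fp, x$fn, x$tn, x$sen, x$acc, x$fpr_per_hour))
  invisible(x)
}

#' Inter-ictal hours available for false alarms
#'
#' Total record time minus ictal and pre-ictal spans and minus the
#' SPH+SOP span following each alarm (overlaps merged).
#'
#' @param record An [eeg_record()].
#' @param alarms Alarm times in seconds.
#' @param config A [scoring_config()].
#' @param pil_minutes Pre-ictal period length in minutes.
#' @return Hours (numeric scalar).
#' @export
interictal_hours <- function(record, alarms = numeric(),
                             config = scoring_config(), pil_minutes = 5) {
  dur <- record_duration(record)
  spans <- list()
  for (i in seq_len(nrow(record$annotations))) {
    on <- record$annotations$onset[i]
    spans[[length(spans) + 1L]] <- c(max(0, on - pil_minutes * 60),
                                     min(dur, record$annotations$offset[i]))
  }
  for (t in alarms) {
    spans[[length(spans) + 1L]] <- c(t, min(dur, t + config$sph_s +
                                              config$sop_s))
  }
  excluded <- merge_span_length(spans, dur)
  (dur - excluded) / 3600
}

merge_span_length <- function(spans, dur) {
  if (!length(spans)) return(0)
  m <- do.call(rbind, spans)
  m[, 1] <- pmax(m[, 1], 0); m[, 2] <- pmin(m[, 2], dur)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (!nrow(m)) return(0)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], m[i, 2])
    } else {
      tot <- tot + cur[2] - cur[1]
      cur <- m[i, ]
    }
  }
  tot + cur[2] - cur[1]
}

#' Rank-based (Mann-Whitney) AUC
#'
#' @param probs Numeric scores (higher = more pre-ictal).
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified holdout split
#'
#' @param data A [labeled_dataset()].
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return A list with `train` and `test` datasets.
#' @export
split_holdout <- function(data, fraction = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  idx_tr <- integer(0)
  for (cls in unique(data$y)) {
    idx <- which(data$y == cls)
    n_tr <- round(length(idx) * fraction)
    idx_tr <- c(idx_tr, sample(idx, n_tr))
  }
  idx_tr <- sort(idx_tr)
  idx_te <- setdiff(seq_along(data$y), idx_tr)
  if (length(unique(data$y[idx_tr])) < 2L ||
      length(unique(data$y[idx_te])) < 2L) {
    warning("a class is absent from one side of the split")
  }
  subset_ld <- function(i) labeled_dataset(data$x[i, , drop = FALSE],
                                           data$y[i], data$patient[i],
                                           data$id[i])
  list(train = subset_ld(idx_tr), test = subset_ld(idx_te))
}

#' Leave-one-seizure-out folds
#'
#' @param seizure_ids Identifier per window naming the seizure (or record)
#'   it belongs to.
#' @return A list of folds, each with `test` (logical mask) and `held_out`.
#' @export
loso_folds <- function(seizure_ids) {
  ids <- unique(seizure_ids)
  if (length(ids) < 2L) stop("leave-one-seizure-out needs at least 2 seizures")
  lapply(ids, function(id) list(held_out = id, test = seizure_ids == id))
}

#' Leave-one-patient-out (cross-subject) folds
#'
#' @param patient_ids Patient identifier per window.
#' @return A list of folds, each with `test` (logical mask) and `held_out`.
#' @export
cross_subject_folds <- function(patient_ids) {
  ids <- unique(patient_ids)
  if (length(ids) < 2L) stop("cross-subject CV needs at least 2 patients")
  lapply(ids, function(id) list(held_out = id, test = patient_ids == id))
}
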