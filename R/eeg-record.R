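#' Construct a multichannel EEG record
#'
#' The central in-memory container: a channels x samples matrix in
#' microvolts with one shared sampling rate, channel labels, and a table of
#' seizure annotations. Sampling rates outside the 200-400 Hz range usual
#' for clinical scalp EEG are accepted with a warning.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of montage names; defaults to
#'   `CH1..CHn`.
#' @param patient_id Free-text identifier.
#' @param annotations A data frame as returned by [seizure_annotations()],
#'   or `NULL`.
#' @return An `eeg_record` object.
#' @export
eeg_record <- function(data, fs, channel_labels = NULL, patient_id = "",
                       annotations = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), is.numeric(fs), fs > 0)
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(nch))
  stopifnot(length(channel_labels) == nch)
  if (fs < 200 || fs > 400) {
    warning(sprintf("sampling rate %g Hz is outside the usual 200-400 Hz range", fs))
  }
  dur <- ncol(data) / fs
  if (is.null(annotations)) annotations <- seizure_annotations()
  validate_annotations(annotations, dur)
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 patient_id = patient_id, annotations = annotations),
            class = "eeg_record")
}

#' Build a seizure annotation table
#'
#' Times are seconds from record start; the event occupies the half-open
#' interval `[onset, offset)`. `channels` is a list column of affected
#' channel labels; an empty vector means all channels.
#'
#' @param onset,offset Numeric vectors of event times in seconds.
#' @param label Event labels (recycled).
#' @param channels List of character vectors (recycled), or `NULL`.
#' @return A data frame with columns `onset`, `offset`, `label`, `channels`.
#' @export
seizure_annotations <- function(onset = numeric(), offset = numeric(),
                                label = "seiz", channels = NULL) {
  n <- length(onset)
  stopifnot(length(offset) == n)
  if (is.null(channels)) channels <- rep(list(character(0)), n)
  if (!is.list(channels)) channels <- list(channels)
  data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
             label = rep_len(as.character(label), n),
             channels = I(rep_len(channels, n)))
}

validate_annotations <- function(ann, duration) {
  if (nrow(ann) == 0L) return(invisible(ann))
  if (any(ann$onset < 0) || any(ann$offset <= ann$onset) ||
      any(ann$offset > duration + 1e-9)) {
    stop("annotations must satisfy 0 <= onset < offset <= record duration")
  }
  invisible(ann)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, record_duration(x)))
  if (nzchar(x$patient_id)) cat("  patient:", x$patient_id, "\n")
  cat(sprintf("  %d seizure annotation(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Record duration in seconds
#' @param record An [eeg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) ncol(record$data) / record$fs
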