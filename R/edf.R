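## Minimal EDF+C reader/writer.
##
## 16-bit little-endian samples, one-second data records, one "EDF
## Annotations" signal carrying time-stamped annotation lists (TALs).
## Channel-specific annotation detail travels in the sidecar CSV dialect
## (see read_tuh_labels / write_tuh_labels); TALs carry onset, duration and
## label only.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field '%s' exceeds %d chars", x, width))
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write an EEG record as EDF+
#'
#' Samples are scaled to 16-bit integers over a symmetric per-channel
#' physical range (so zero is represented exactly) and written as EDF+C
#' with one-second data records; seizure annotations are embedded as TALs.
#' Records whose duration is not a whole number of seconds are zero-padded
#' to the next second with a warning.
#'
#' @param record An [eeg_record()]; `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  if (any(!is.finite(record$data))) stop("record contains non-finite samples")
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  data <- record$data
  nch <- nrow(data)
  n <- ncol(data)
  if (n %% fs != 0) {
    warning("record padded with zeros to a whole number of seconds")
    pad <- fs - n %% fs
    data <- cbind(data, matrix(0, nch, pad))
    n <- ncol(data)
  }
  n_rec <- n %/% fs

  ## physical range: symmetric integer bound per channel, digital +-32767
  pmax_ch <- pmax(ceiling(apply(abs(data), 1, max)), 1)
  dig <- matrix(0L, nch, n)
  for (ch in seq_len(nch)) {
    dig[ch, ] <- as.integer(round(data[ch, ] / pmax_ch[ch] * 32767))
  }

  ## annotation TALs: one timestamp TAL per record; all events in record 1
  tal_time <- function(t) {
    s <- formatC(t, format = "f", digits = 3)
    s <- sub("\\.?0+$", "", s)
    if (!startsWith(s, "-")) s <- paste0("+", s)
    s
  }
  ev <- character(0)
  ann <- record$annotations
  if (nrow(ann)) {
    ev <- vapply(seq_len(nrow(ann)), function(i) {
      paste0(tal_time(ann$onset[i]), "\x15",
             sub("\\.?0+$", "", formatC(ann$offset[i] - ann$onset[i],
                                        format = "f", digits = 3)),
             "\x14", ann$label[i], "\x14")
    }, character(1))
  }
  rec_tals <- lapply(seq_len(n_rec), function(r) {
    ts <- paste0(tal_time(r - 1), "\x14\x14")
    if (r == 1L && length(ev)) paste0(ts, paste0(ev, collapse = "")) else ts
  })
  ann_bytes <- max(vapply(rec_tals, nchar, integer(1), type = "bytes")) + 2L
  if (ann_bytes %% 2L) ann_bytes <- ann_bytes + 1L
  ann_spr <- ann_bytes %/% 2L

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8))
  wr(edf_pad(substr(paste0("X X X ", record$patient_id), 1, 80), 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(header_bytes, 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad(1, 8)); wr(edf_pad(ns, 4))
  labels <- c(substr(record$channel_labels, 1, 16), "EDF Annotations")
  for (l in labels) wr(edf_pad(l, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(if (i <= nch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) -pmax_ch[i] else -1, 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) pmax_ch[i] else 1, 8))
  for (i in seq_len(ns)) wr(edf_pad(-32767, 8))
  for (i in seq_len(ns)) wr(edf_pad(32767, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(if (i <= nch) fs else ann_spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      writeBin(dig[ch, idx], con, size = 2, endian = "little")
    }
    tal <- rec_tals[[r]]
    raw_tal <- c(charToRaw(tal), as.raw(0L))
    raw_tal <- c(raw_tal, raw(ann_bytes - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into an EEG record
#'
#' Signals are rescaled to physical units; an embedded "EDF Annotations"
#' channel is parsed into the record's annotation table. All ordinary
#' signals must share one sampling rate; with `strict = TRUE` a mismatch is
#' an error, otherwise mismatched channels are dropped with a warning.
#'
#' @param path EDF file path.
#' @param strict Error on per-channel sampling-rate mismatch?
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (nchar(s, type = "bytes") < w) stop("corrupt EDF header: truncated file")
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("corrupt EDF header: bad version field")
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1) {
    stop("corrupt EDF header: unparseable numeric fields")
  }
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)

  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  fs_all <- spr[sig] / rec_dur
  keep <- sig
  if (length(unique(fs_all)) > 1L) {
    if (strict) stop("per-channel sampling rates differ; strict mode rejects the file")
    fs_mode <- as.numeric(names(sort(table(fs_all), decreasing = TRUE))[1])
    drop <- sig[fs_all != fs_mode]
    warning(sprintf("dropping %d channel(s) with mismatched sampling rate", length(drop)))
    keep <- setdiff(sig, drop)
  }
  fs <- spr[keep[1]] / rec_dur

  out <- matrix(0, length(keep), n_rec * spr[keep[1]])
  tal_raw <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        tal_raw[[length(tal_raw) + 1L]] <- readBin(con, "raw", spr[i] * 2L)
      } else {
        v <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        j <- match(i, keep)
        if (!is.na(j)) {
          out[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
        }
      }
    }
  }
  for (j in seq_along(keep)) {
    i <- keep[j]
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    out[j, ] <- (out[j, ] - dig_min[i]) * g + phys_min[i]
  }

  ann <- parse_tals(tal_raw)
  rec <- eeg_record(out, fs, channel_labels = labels[keep],
                    patient_id = sub("^X X X ?", "", patient),
                    annotations = ann)
  rec
}

parse_tals <- function(tal_raw) {
  onset <- numeric(); offset <- numeric(); label <- character()
  for (blk in tal_raw) {
    txt <- rawToChar(blk[blk != as.raw(0)])
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
    ## events may share a block with the timestamp TAL prefix
    for (tal in tals) {
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
      t0 <- suppressWarnings(as.numeric(head[1]))
      dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
      if (is.na(t0)) next
      for (lab in parts[-1]) {
        if (!nzchar(lab)) next
        onset <- c(onset, t0); offset <- c(offset, t0 + dur)
        label <- c(label, lab)
      }
    }
  }
  seizure_annotations(onset, offset, if (length(label)) label else "seiz")
}

#' Read TUH-style per-channel seizure labels
#'
#' Parses a CSV with header `channel,start_time,stop_time,label` (one row
#' per channel-event). Rows naming unknown channels or with
#' `stop_time <= start_time` are skipped with a warning; out-of-range times
#' are clipped to the record with a warning. Rows sharing identical start,
#' stop and label are merged into one annotation listing all channels.
#'
#' @param path CSV file path.
#' @param record The [eeg_record()] the labels refer to.
#' @return An annotation data frame (see [seizure_annotations()]).
#' @export
read_tuh_labels <- function(path, record) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_time", "stop_time", "label")
  if (!all(need %in% names(df))) {
    stop("label file must have columns channel,start_time,stop_time,label")
  }
  if (nrow(df) == 0L) return(seizure_annotations())
  known <- df$channel %in% record$channel_labels
  if (any(!known)) {
    warning(sprintf("skipping %d row(s) with unknown channel name", sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  bad <- df$stop_time <= df$start_time
  if (any(bad)) {
    warning(sprintf("skipping %d row(s) with stop_time <= start_time", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(seizure_annotations())
  dur <- record_duration(record)
  if (any(df$start_time < 0) || any(df$stop_time > dur)) {
    warning("clipping annotation times to the record extent")
    df$start_time <- pmax(df$start_time, 0)
    df$stop_time <- pmin(df$stop_time, dur)
  }
  key <- paste(df$start_time, df$stop_time, df$label, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  onset <- vapply(groups, function(g) g$start_time[1], numeric(1))
  offset <- vapply(groups, function(g) g$stop_time[1], numeric(1))
  label <- vapply(groups, function(g) g$label[1], character(1))
  channels <- lapply(groups, function(g) unique(g$channel))
  seizure_annotations(unname(onset), unname(offset), unname(label),
                      unname(channels))
}

#' Write annotations in the TUH-style CSV dialect
#'
#' @param record An [eeg_record()] whose annotations should be exported.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuh_labels <- function(record, path) {
  ann <- record$annotations
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    chs <- ann$channels[[i]]
    if (!length(chs)) chs <- record$channel_labels
    rows[[i]] <- data.frame(channel = chs, start_time = ann$onset[i],
                            stop_time = ann$offset[i], label = ann$label[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(channel = character(), start_time = numeric(),
               stop_time = numeric(), label = character())
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
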