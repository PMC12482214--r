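test_that("EDF round trip preserves signal within one quantization step", {
  ts <- tiny_sim(seed = 4, n_channels = 3, pil_minutes = 1, ratio = 2)
  rec <- ts$sim$record
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$annotations$onset, rec$annotations$onset)
  expect_equal(back$annotations$offset, rec$annotations$offset)
  step <- 2 * max(ceiling(apply(abs(rec$data), 1, max))) / 65534
  expect_lt(max(abs(back$data - rec$data)), step)
})

test_that("a constant-zero record round-trips exactly", {
  rec <- eeg_record(matrix(0, 1, 500), 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(max(abs(back$data)), 0)
  expect_equal(dim(back$data), dim(rec$data))
})

test_that("a single annotation keeps its onset and offset", {
  set.seed(1)
  rec <- eeg_record(matrix(rnorm(250 * 200), 1), 250,
                    annotations = seizure_annotations(100, 160, "seiz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(nrow(back$annotations), 1L)
  expect_equal(back$annotations$onset, 100)
  expect_equal(back$annotations$offset, 160)
  expect_equal(back$annotations$label, "seiz")
})

test_that("writer rejects non-finite samples; reader rejects junk files", {
  bad <- eeg_record(matrix(0, 1, 250), 250)
  bad$data[1, 5] <- NaN
  expect_error(write_edf(bad, tempfile()), "non-finite")
  junk <- withr::local_tempfile(fileext = ".edf")
  writeLines("not an edf file", junk)
  expect_error(read_edf(junk), "corrupt")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "not found")
})

test_that("mixed per-channel sampling rates error in strict mode", {
  # hand-craft a 2-channel EDF whose channels disagree on samples/record
  rec <- eeg_record(matrix(rnorm(500), 2, 250), 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # samples-per-record fields for ns=3 signals start at byte offset
  # 256 + 3*(16+80+8+8+8+8+8+80) and are 8 bytes each
  off <- 256 + 3 * 216
  raw[(off + 1):(off + 8)] <- charToRaw(formatC("125", width = -8))
  # record payload: ch1 now reads 125 samples; rebuild a consistent body
  writeBin(raw[1:(256 * 4)], path2 <- withr::local_tempfile(fileext = ".edf"))
  con <- file(path2, "ab")
  writeBin(integer(125), con, size = 2, endian = "little")
  writeBin(integer(250), con, size = 2, endian = "little")
  writeBin(rep(as.raw(0), 60), con)
  close(con)
  # fix n_records to 1 and annotation spr to 30
  raw2 <- readBin(path2, "raw", file.info(path2)$size)
  raw2[237:244] <- charToRaw(formatC("1", width = -8))
  off3 <- 256 + 3 * 216 + 2 * 8
  raw2[(off3 + 1):(off3 + 8)] <- charToRaw(formatC("30", width = -8))
  writeBin(raw2, path2)
  expect_error(read_edf(path2, strict = TRUE), "strict")
  w <- capture_warnings(ok <- read_edf(path2, strict = FALSE))
  expect_true(any(grepl("mismatch", w)))
  expect_equal(nrow(ok$data), 1L)
})

test_that("sampling rates outside 200-400 Hz warn at construction", {
  expect_warning(eeg_record(matrix(0, 1, 100), 100), "200-400")
  expect_silent(eeg_record(matrix(0, 1, 100), 250))
})

test_that("TUH label parsing merges, skips and clips as specified", {
  rec <- eeg_record(matrix(0, 2, 250 * 300), 250,
                    channel_labels = c("FP1", "FP2"))
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("channel,start_time,stop_time,label", path)
  expect_equal(nrow(read_tuh_labels(path, rec)), 0L)

  writeLines(c("channel,start_time,stop_time,label",
               "FP1,100,160,seiz",
               "FP2,100,160,seiz"), path)
  ann <- read_tuh_labels(path, rec)
  expect_equal(nrow(ann), 1L)
  expect_setequal(ann$channels[[1]], c("FP1", "FP2"))

  writeLines(c("channel,start_time,stop_time,label",
               "FP1,100,160,seiz",
               "FP1,200,150,seiz"), path)
  expect_warning(ann2 <- read_tuh_labels(path, rec), "stop_time")
  expect_equal(nrow(ann2), 1L)

  writeLines(c("channel,start_time,stop_time,label",
               "BOGUS,100,160,seiz"), path)
  expect_warning(ann3 <- read_tuh_labels(path, rec), "unknown channel")
  expect_equal(nrow(ann3), 0L)

  writeLines(c("channel,start_time,stop_time,label",
               "FP1,100,9999,seiz"), path)
  expect_warning(ann4 <- read_tuh_labels(path, rec), "clip")
  expect_equal(ann4$offset, 300)
})

test_that("label CSV writer round-trips through the reader", {
  rec <- eeg_record(matrix(0, 2, 250 * 300), 250,
                    channel_labels = c("FP1", "FP2"),
                    annotations = seizure_annotations(
                      c(50, 120), c(70, 130), "seiz",
                      channels = list("FP1", character(0))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tuh_labels(rec, path)
  ann <- read_tuh_labels(path, rec)
  expect_equal(ann$onset, c(50, 120))
  expect_setequal(ann$channels[[2]], c("FP1", "FP2"))
})

test_that("a one-channel minimal record is accepted", {
  rec <- eeg_record(matrix(sin(1:500), 1, 500), 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_equal(nrow(read_edf(path)$data), 1L)
})
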