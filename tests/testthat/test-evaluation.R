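test_that("windows intersecting the pre-ictal span are labeled PIL", {
  rec <- eeg_record(matrix(0, 1, 250 * 1200), 250,
                    annotations = seizure_annotations(1000, 1010))
  grid <- segment_eeg(rec, 4)
  win <- label_windows(rec, grid, pil_minutes = 5)
  expect_equal(sum(win$label == "PIL"), 75L)  # [700, 1000) / 4 s
  expect_true(all(win$t_start[win$label == "PIL"] >= 700))
  # a wider window straddling the 700 s boundary is PIL by intersection
  wide <- label_windows(rec, grid, pil_minutes = 5, width = 2L,
                        stride = 1L)
  expect_equal(wide$label[wide$t_start == 696], "PIL")
  # ictal-overlapping windows are excluded
  expect_true(all(win$label[win$t_start %in% c(1000, 1004, 1008)] ==
                    "excluded"))
})

test_that("pre-ictal spans clip at the record start", {
  rec <- eeg_record(matrix(0, 1, 250 * 400), 250,
                    annotations = seizure_annotations(100, 110))
  win <- label_windows(rec, segment_eeg(rec, 4), pil_minutes = 5)
  expect_equal(sum(win$label == "PIL"), 25L)  # [0, 100) / 4 s
  rec0 <- eeg_record(matrix(0, 1, 250 * 400), 250)
  expect_warning(w0 <- label_windows(rec0, segment_eeg(rec0, 4)),
                 "no annotations")
  expect_true(all(w0$label == "IIL"))
})

test_that("alarm generation honors threshold, persistence, refractory", {
  rec <- eeg_record(matrix(0, 1, 250 * 400), 250)
  grid <- segment_eeg(rec, 4)
  win <- window_spans(grid)
  cfg <- scoring_config(threshold = 0.5, persistence = 1L)
  expect_length(alarms_from_probs(rep(0, nrow(win)), win, cfg), 0)

  probs <- rep(0, nrow(win)); probs[10] <- 0.9
  a <- alarms_from_probs(probs, win, cfg)
  expect_equal(a, win$t_end[10])

  cfg3 <- scoring_config(threshold = 0.5, persistence = 3L)
  probs2 <- rep(0, nrow(win)); probs2[10:11] <- 0.9
  expect_length(alarms_from_probs(probs2, win, cfg3), 0)
  probs2[12] <- 0.9
  expect_equal(alarms_from_probs(probs2, win, cfg3), win$t_end[12])

  # refractory suppresses a second alarm inside the SOP window
  cfgr <- scoring_config(threshold = 0.5, persistence = 1L,
                         sop_minutes = 1)
  probs3 <- rep(0.9, nrow(win))
  a3 <- alarms_from_probs(probs3, win, cfgr)
  expect_true(all(diff(a3) >= 60))
})

test_that("SPH/SOP scoring reproduces the worked truth table", {
  cfg <- scoring_config(sph_minutes = 5, sop_minutes = 10)
  ann <- seizure_annotations(1000, 1010)
  # onset 1000 in [500+300, 500+300+600] = [800, 1400] -> TP
  s1 <- score_alarms(500, ann, cfg)
  expect_equal(c(s1$tp, s1$fp, s1$fn), c(1L, 0L, 0L))
  # alarm at 950: onset inside the SPH [950, 1250) -> FP and FN
  s2 <- score_alarms(950, ann, cfg)
  expect_equal(c(s2$tp, s2$fp, s2$fn), c(0L, 1L, 1L))
  # no alarms at all -> FN
  s3 <- score_alarms(numeric(0), ann, cfg)
  expect_equal(c(s3$tp, s3$fp, s3$fn), c(0L, 0L, 1L))
})

test_that("every seizure is credited exactly once across random cases", {
  set.seed(12)
  cfg <- scoring_config(sph_minutes = 1, sop_minutes = 5)
  for (rep in 1:20) {
    onsets <- sort(runif(sample(1:4, 1), 100, 3000))
    ok <- diff(c(0, onsets)) > 400
    onsets <- onsets[ok]
    if (!length(onsets)) next
    alarms <- sort(runif(sample(0:6, 1), 0, 3000))
    s <- score_alarms(alarms, seizure_annotations(onsets, onsets + 10),
                      cfg)
    expect_equal(s$tp + s$fn, length(onsets))
    expect_equal(s$tp + s$fp, length(alarms))
    # adding an alarm never decreases TP
    s2 <- score_alarms(c(alarms, onsets[1] - 120),
                       seizure_annotations(onsets, onsets + 10), cfg)
    expect_gte(s2$tp, s$tp)
  }
})

test_that("metric arithmetic and zero-denominator flags are correct", {
  m <- compute_metrics(tp = 9, fp = 0, fn = 1, tn = 0,
                       interictal_hours = 10)
  expect_equal(m$sen, 0.9)
  m2 <- compute_metrics(tp = 0, fp = 2, fn = 0, tn = 0,
                        interictal_hours = 10)
  expect_equal(m2$fpr_per_hour, 0.2)
  m3 <- compute_metrics(tp = 1, fp = 1, fn = 1, tn = 97,
                        interictal_hours = 1)
  expect_equal(m3$acc, 0.98)
  m4 <- compute_metrics(tp = 0, fp = 0, fn = 0, tn = 0)
  expect_true(all(c("sen", "acc", "fpr_per_hour") %in% m4$undefined))
  expect_true(is.na(m4$sen))
})

test_that("inter-ictal hours exclude seizure context and alarm windows", {
  rec <- eeg_record(matrix(0, 1, 250 * 3600), 250,
                    annotations = seizure_annotations(1800, 1850))
  cfg <- scoring_config(sph_minutes = 1, sop_minutes = 4)
  h0 <- interictal_hours(rec, numeric(0), cfg, pil_minutes = 5)
  expect_equal(h0, (3600 - 300 - 50) / 3600)
  # an alarm long before the seizure removes SPH+SOP more
  h1 <- interictal_hours(rec, 600, cfg, pil_minutes = 5)
  expect_equal(h1, (3600 - 300 - 50 - 300) / 3600)
  # overlapping exclusions are not double counted
  h2 <- interictal_hours(rec, c(600, 700), cfg, pil_minutes = 5)
  expect_equal(h2, (3600 - 300 - 50 - 400) / 3600)
})

test_that("rank AUC behaves and agrees with an independent package", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(14)
  probs <- runif(400)
  labs <- rbinom(400, 1, 0.3)
  a <- auc_score(probs, labs)
  expect_equal(a + auc_score(1 - probs, labs), 1)
  # independent of scores -> near 0.5 within 3 SE
  n1 <- sum(labs); n0 <- sum(labs == 0)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * se)
  expect_error(auc_score(probs, rep(1, 400)), "both classes")
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(labs, probs, quiet = TRUE,
                                           direction = "<")))
  expect_equal(a, oracle, tolerance = 1e-12)
})

test_that("holdout split is stratified, sized and seeded", {
  d <- toy_dataset(20, 80)
  sp <- split_holdout(d, 0.8, seed = 3)
  expect_equal(length(sp$train$y), 80)
  expect_equal(length(sp$test$y), 20)
  expect_equal(sum(sp$train$y == 1), 16)
  expect_equal(sum(sp$test$y == 1), 4)
  sp2 <- split_holdout(d, 0.8, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
})

test_that("cross-validation folds partition without leakage", {
  sz <- rep(1:3, times = c(5, 7, 4))
  folds <- loso_folds(sz)
  expect_length(folds, 3)
  cover <- rowSums(sapply(folds, `[[`, "test"))
  expect_true(all(cover == 1))
  pats <- rep(c("a", "b", "c", "d"), each = 6)
  cf <- cross_subject_folds(pats)
  expect_length(cf, 4)
  for (f in cf) {
    expect_false(any(pats[!f$test] == f$held_out))
  }
  expect_error(loso_folds(rep(1, 5)), "at least 2")
})
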