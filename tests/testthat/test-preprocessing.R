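test_that("segmentation discards trailing partial windows", {
  rec60 <- eeg_record(matrix(0, 1, 60 * 250), 250)
  expect_equal(segment_eeg(rec60, 4)$k, 15L)
  rec61 <- eeg_record(matrix(0, 1, 61 * 250), 250)
  expect_equal(segment_eeg(rec61, 4)$k, 15L)
  rec260 <- eeg_record(matrix(0, 1, 10 * 1040), 260)
  g <- segment_eeg(rec260, 4)
  expect_equal(g$window_samples, 1040L)
  expect_equal(g$k, 10L)
  expect_error(segment_eeg(eeg_record(matrix(0, 1, 500), 250), 4),
               "shorter")
})

test_that("wavelet decomposition matches frozen reference coefficients", {
  # db4, symmetric extension, x = 1..10 (values frozen from an
  # independent high-precision run)
  wd <- wavedec(1:10, "db4", 1L)
  expect_equal(wd$approx,
               c(7.06453146, 4.23073611, 1.41360717, 2.83605428,
                 5.66448141, 8.49181772, 11.32561307, 14.14274202),
               tolerance = 1e-8)
  expect_equal(wd$details[[1]],
               c(0.0237131306, 0.0409620864, -0.064675217, 0, 0,
                 -0.0237131306, -0.0409620864, 0.064675217),
               tolerance = 1e-7)
})

test_that("multi-level transform reconstructs perfectly", {
  set.seed(5)
  for (wav in c("haar", "db2", "db4")) {
    for (n in c(100, 250, 1000)) {
      x <- rnorm(n)
      lev <- max(1L, floor(log2(n)) - 2L)
      expect_equal(waverec(wavedec(x, wav, lev)), x, tolerance = 1e-8)
    }
  }
})

test_that("universal threshold follows sigma * sqrt(2 log P)", {
  set.seed(1)
  d <- rnorm(512)
  d <- (d - mean(d)) / sd(d) + mean(d)  # sd exactly 1
  d <- d / sd(d)
  expect_equal(universal_threshold(d, 1024), 3.723297411059034,
               tolerance = 1e-10)
  expect_equal(universal_threshold(2 * d, 1024),
               2 * universal_threshold(d, 1024))
  expect_equal(universal_threshold(rep(3, 100), 1024), 0)
  expect_error(universal_threshold(d, 1), "P")
})

test_that("soft-threshold denoising shrinks and preserves structure", {
  cfg <- mraf_config()
  expect_identical(soft_threshold_denoise(rep(0, 512), cfg), rep(0, 512))
  expect_error(soft_threshold_denoise(c(1, NA, 3), cfg), "non-finite")

  # noise variance strictly reduced around a known clean component
  set.seed(7)
  t <- (1:1024) / 256
  clean <- sin(2 * pi * 5 * t)
  noisy <- clean + rnorm(1024, sd = 0.3)
  den <- soft_threshold_denoise(noisy, cfg)
  expect_lt(var(den - clean), var(noisy - clean))
  expect_equal(length(den), 1024L)

  # repeated shrinkage is non-expansive in energy
  d1 <- soft_threshold_denoise(noisy, cfg)
  d2 <- soft_threshold_denoise(d1, cfg)
  expect_lte(sum(d2^2), sum(d1^2) + 1e-9)
})

test_that("detail coefficients never grow in magnitude after shrinkage", {
  set.seed(8)
  x <- rnorm(512) + sin((1:512) / 10)
  wd_in <- wavedec(x, "db4", 4L)
  sigma <- mad(wd_in$details[[1]], constant = 1.4826)
  for (l in 1:4) {
    thr <- universal_threshold(wd_in$details[[l]], 512, sigma = sigma)
    shrunk <- sign(wd_in$details[[l]]) *
      pmax(abs(wd_in$details[[l]]) - thr, 0)
    expect_true(all(abs(shrunk) <= abs(wd_in$details[[l]]) + 1e-12))
    expect_gte(thr, 0)
  }
})

test_that("in-band content passes the adaptive band filter", {
  fs <- 250
  t <- (1:1000) / fs
  x <- sin(2 * pi * 10 * t)
  y <- mraf_filter(x, fs, band_definition("alpha", 8, 13))
  half <- 501:1000
  expect_gte(cor(y[half], x[half]), 0.95)
  expect_equal(length(y), 1000L)
  expect_identical(mraf_filter(rep(0, 1000), fs,
                               band_definition("alpha", 8, 13)),
                   rep(0, 1000))
  expect_error(mraf_filter(x, fs, band_definition("wide", 10, 200)),
               "Nyquist")
})

test_that("out-of-band artifacts are attenuated by >= 10 dB", {
  fs <- 250
  t <- (1:1000) / fs
  x <- sin(2 * pi * 40 * t) + 5 * sin(2 * pi * 1 * t)
  y <- mraf_filter(x, fs, band_definition("gamma", 30, 100))
  p_in <- oracle_band_power(x, fs, 0.5, 2)
  p_out <- oracle_band_power(y, fs, 0.5, 2)
  expect_gte(10 * log10(p_in / p_out), 10)
})

test_that("band outputs concentrate >= 90% of power in band", {
  ts <- tiny_sim(seed = 3, pil_minutes = 1, ratio = 2)
  seg <- ts$sim$record$data[1, 1:1000]
  fs <- 250
  for (b in default_bands(fs)) {
    y <- mraf_filter(seg, fs, b)
    tot <- oracle_band_power(y, fs, 0, fs / 2)
    inb <- oracle_band_power(y, fs, max(0, b$f_lo - 1), b$f_hi + 1)
    expect_gte(inb / tot, 0.90)
  }
})

test_that("band tensor has the documented shape and is consistent", {
  ts <- tiny_sim(seed = 5, n_channels = 2, pil_minutes = 1, ratio = 2)
  rec <- ts$sim$record
  grid <- segment_eeg(rec, 4)
  bands <- default_bands(rec$fs)
  filt <- decompose_bands(rec, grid, bands)
  expect_equal(dim(filt), c(6L, 2L, grid$k, 1000L))
  expect_true(all(is.finite(filt)))
  # single-band request equals the direct filter call
  seg <- rec$data[2, 1:1000]
  direct <- mraf_filter(seg, rec$fs, bands[[1]])
  expect_equal(filt[1, 2, 1, ], direct, tolerance = 1e-10)
  # disjoint-band energies approximately partition the denoised signal
  den <- soft_threshold_denoise(seg)
  e_fb <- sum((den - mean(den))^2)
  e_sum <- sum(filt[c("alpha", "beta", "gamma", "theta", "delta"),
                    2, 1, ]^2)
  expect_lt(abs(e_sum - e_fb) / e_fb, 0.2)
})
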