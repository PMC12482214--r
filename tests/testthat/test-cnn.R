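test_that("parameter count matches the closed-form arithmetic", {
  m <- build_model(c(126, 64))
  # sum(k_h*k_w*in_ch*out_ch + out_ch) over convs plus dense terms
  expect_equal(count_params(m),
               (3 * 3 * 1 * 8 + 8) + (5 * 5 * 8 * 16 + 16) +
                 (3 * 3 * 16 * 32 + 32) +
                 (1984 * 256 + 256) + (256 * 128 + 128) + (128 * 2 + 2))
})

test_that("layer output shapes follow the stride/pool arithmetic", {
  m <- build_model(c(126, 64))
  expect_equal(m$shapes$conv1, c(126, 64, 8))
  expect_equal(m$shapes$pool1, c(63, 32, 8))
  expect_equal(m$shapes$conv2, c(63, 11, 16))
  expect_equal(m$shapes$pool2, c(31, 5, 16))
  expect_equal(m$shapes$conv3, c(31, 2, 32))
  expect_equal(m$shapes$flatten, 1984)
})

test_that("too-small inputs raise a sizing error naming the layer", {
  expect_error(build_model(c(3, 8)), "too small")
})

test_that("weight initialization is reproducible from the seed", {
  a <- build_model(c(18, 8), cnn_config(seed = 3))
  b <- build_model(c(18, 8), cnn_config(seed = 3))
  expect_identical(a$layers, b$layers)
  c <- build_model(c(18, 8), cnn_config(seed = 4))
  expect_false(identical(a$layers[[1]]$W, c$layers[[1]]$W))
})

test_that("conv and pool backward passes match numeric gradients", {
  sv <- asNamespace("spectralverge")
  set.seed(1)
  geom <- sv$conv_geom(c(8L, 6L, 2L), c(3L, 3L), c(1L, 2L))
  gather <- Matrix::sparseMatrix(
    i = seq_along(geom$idx), j = as.vector(geom$idx), x = 1,
    dims = c(length(geom$idx), geom$hp * geom$wp * 2L))
  layer <- list(type = "conv", W = matrix(rnorm(3 * 18), 3, 18),
                b = rnorm(3), geom = geom, gather = gather)
  x <- array(rnorm(8 * 6 * 2 * 3), c(8, 6, 2, 3))
  R <- array(rnorm(geom$oh * geom$ow * 3 * 3), c(geom$oh, geom$ow, 3, 3))
  scalar <- function(l, xx) sum(sv$conv_forward(l, xx)$out * R)
  fw <- sv$conv_forward(layer, x)
  bk <- sv$conv_backward(layer, R, fw$cache)
  eps <- 1e-6
  for (i in sample(length(layer$W), 12)) {
    lp <- layer; lp$W[i] <- lp$W[i] + eps
    lm <- layer; lm$W[i] <- lm$W[i] - eps
    num <- (scalar(lp, x) - scalar(lm, x)) / (2 * eps)
    expect_equal(bk$dW[i], num, tolerance = 1e-4)
  }
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (scalar(layer, xp) - scalar(layer, xm)) / (2 * eps)
    expect_equal(bk$dx[i], num, tolerance = 1e-4)
  }
  pg <- sv$pool_geom(c(8L, 6L, 2L))
  pl <- list(type = "pool", geom = pg)
  pf <- sv$pool_forward(pl, x)
  Rp <- array(rnorm(prod(dim(pf$out))), dim(pf$out))
  pb <- sv$pool_backward(pl, Rp, pf$cache)
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(sv$pool_forward(pl, xp)$out * Rp) -
              sum(sv$pool_forward(pl, xm)$out * Rp)) / (2 * eps)
    expect_equal(pb$dx[i], num, tolerance = 1e-4)
  }
})

test_that("training stops by the patience rule and the epoch cap", {
  # scripted strictly-rising validation error: stop at epoch 11
  expect_equal(early_stopping_epoch(seq(0.1, by = 0.01,
                                        length.out = 150), 10), 11)
  # a dip resets the consecutive-rise counter
  errs <- c(0.5, 0.6, 0.7, 0.3, seq(0.31, by = 0.01, length.out = 20))
  expect_equal(early_stopping_epoch(errs, 10), 14)
  # cap honored when the error never rises
  expect_equal(early_stopping_epoch(rep(0.2, 500), 10, 150), 150)

  # live training respects max_epochs = 1
  set.seed(2)
  X <- array(rnorm(18 * 8 * 1 * 40), c(18, 8, 1, 40))
  y <- rep(c(0L, 1L), 20)
  cfg <- cnn_config(batch = 20, max_epochs = 1, seed = 1)
  clf <- train_cnn(build_model(c(18, 8), cfg),
                   list(x = X[, , , 1:30, drop = FALSE], y = y[1:30]),
                   list(x = X[, , , 31:40, drop = FALSE], y = y[31:40]),
                   cfg)
  expect_equal(nrow(clf$history), 1L)
  expect_equal(clf$stopped_epoch, 1L)
  expect_error(train_cnn(build_model(c(18, 8), cfg),
                         list(x = X[, , , 1:30, drop = FALSE],
                              y = rep(0L, 30)),
                         list(x = X[, , , 31:40, drop = FALSE],
                              y = y[31:40]), cfg),
               "both classes")
})

test_that("a separable synthetic task is learned to high accuracy", {
  set.seed(4)
  n <- 120
  X <- array(rnorm(18 * 8 * 1 * n), c(18, 8, 1, n))
  y <- rep(c(0L, 1L), n / 2)
  X[3, , , y == 1] <- X[3, , , y == 1] + 3  # disjoint gamma-row ranges
  tr <- 1:96; va <- 97:120
  cfg <- cnn_config(batch = 32, max_epochs = 80, seed = 5)
  clf <- train_cnn(build_model(c(18, 8), cfg),
                   list(x = X[, , , tr, drop = FALSE], y = y[tr]),
                   list(x = X[, , , va, drop = FALSE], y = y[va]), cfg)
  expect_lte(clf$stopped_epoch, 150)
  pp <- predict_proba(clf, X[, , , va, drop = FALSE])
  expect_gte(mean((pp[, "PIL"] > 0.5) == (y[va] == 1)), 0.95)
  expect_gt(mean(pp[y[va] == 1, "PIL"]), mean(pp[y[va] == 0, "PIL"]))

  # training history is reproducible from the seed
  clf2 <- train_cnn(build_model(c(18, 8), cfg),
                    list(x = X[, , , tr, drop = FALSE], y = y[tr]),
                    list(x = X[, , , va, drop = FALSE], y = y[va]), cfg)
  expect_identical(clf$history, clf2$history)
})

test_that("inference is deterministic and produces proper probabilities", {
  set.seed(6)
  m <- build_model(c(18, 8), cnn_config(seed = 7))
  X <- array(rnorm(18 * 8 * 1 * 10), c(18, 8, 1, 10))
  X[, , , 6:10] <- X[, , , 1:5]  # duplicated rows
  p <- predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1:5, ], p[6:10, ])
  expect_error(predict_proba(m, array(0, c(4, 4, 1, 2))), "shape")
})

test_that("ablation variants change the pipeline as documented", {
  expect_error(ablation_variant("bogus"), "unknown")
  expect_true(ablation_variant("no_multiresolution")$fb_only)
  expect_equal(ablation_variant("no_subband_voting")$fusion, "average")
  full <- build_model(c(18, 8), cnn_config(seed = 1))
  shal <- build_model(c(18, 8), shallow_config(cnn_config(seed = 1)))
  expect_lt(count_params(shal), count_params(full))
  ts <- tiny_sim(seed = 2, n_channels = 1, pil_minutes = 1, ratio = 2)
  feats <- extract_features(ts$sim$record, raw_fb = TRUE)
  expect_equal(dim(feats$map)[1], 1L)
  expect_equal(rownames(feats$map), "fb")
})

test_that("sub-band voting fuses hard labels with ties toward inter-ictal", {
  set.seed(8)
  nb <- 3; nch <- 8; w <- 8; n <- 60
  X <- array(rnorm(nb * nch * w * n), c(nb * nch, w, 1, n))
  y <- rep(c(0L, 1L), n / 2)
  for (b in 1:2) {  # signal in two of three bands
    rows <- (seq_len(nch) - 1L) * nb + b
    X[rows[1], , , y == 1] <- X[rows[1], , , y == 1] + 3
  }
  cfg <- cnn_config(batch = 20, max_epochs = 40, seed = 9)
  tr <- 1:40; va <- 41:60
  ens <- train_subband_ensemble(list(x = X[, , , tr, drop = FALSE],
                                     y = y[tr]),
                                list(x = X[, , , va, drop = FALSE],
                                     y = y[va]),
                                nb, nch, cfg, fusion = "majority")
  p <- predict_ensemble(ens, X[, , , va, drop = FALSE])
  # vote fractions live on {0, 1/3, 2/3, 1}; majority > 0.5 = PIL
  expect_true(all(p[, "PIL"] %in% c(0, 1 / 3, 2 / 3, 1)))
  acc <- mean((p[, "PIL"] > 0.5) == (y[va] == 1))
  expect_gte(acc, 0.9)
})
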