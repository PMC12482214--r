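## Lightweight CNN for CSV feature-map windows, implemented with im2col
## matrix operations: three conv layers (8/16/32 filters, 'same' padding,
## the second and third with a 1x3 stride), 2x2 max pooling after the first
## two, dense 256-128-2 with dropout 0.5, ReLU throughout and a softmax
## output, trained by Adam on categorical cross-entropy with early
## stopping on the validation error rate.

#' CNN architecture and training configuration
#'
#' Defaults: conv stack (3x3, 8 filters, stride 1x1), (5x5, 16, stride
#' 1x3), (3x3, 32, stride 1x3) with 2x2/stride-2 max pooling after the
#' first two; dense layers 256, 128, 2 with dropout 0.5 after the first
#' two; ReLU activations and a softmax output; Adam with learning rate
#' 0.001; batch size 100; at most 150 epochs with early stopping after 10
#' consecutive epochs of rising validation error.
#'
#' @param conv List of conv specs, each `list(k, filters, stride)`.
#' @param pool_after Indices of conv layers followed by 2x2 max pooling.
#' @param dense Dense layer widths; the last must be 2.
#' @param dropout Dropout rate after the first two dense layers.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive rising-validation-error epochs that stop
#'   training.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv = list(list(k = c(3, 3), filters = 8,
                                        stride = c(1, 1)),
                                   list(k = c(5, 5), filters = 16,
                                        stride = c(1, 3)),
                                   list(k = c(3, 3), filters = 32,
                                        stride = c(1, 3))),
                       pool_after = c(1, 2),
                       dense = c(256, 128, 2),
                       dropout = 0.5, lr = 0.001, batch = 100L,
                       max_epochs = 150L, patience = 10L, seed = 1L) {
  stopifnot(dense[length(dense)] == 2, batch >= 1, max_epochs >= 1,
            patience >= 1)
  for (cv in conv) stopifnot(all(cv$k >= 1), all(cv$stride >= 1),
                             cv$filters >= 1)
  structure(list(conv = conv, pool_after = pool_after, dense = dense,
                 dropout = dropout, lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = seed),
            class = "cnn_config")
}

conv_out_len <- function(n, s) as.integer(ceiling(n / s))
pool_out_len <- function(n) as.integer(floor(n / 2))

## geometry + gather-index table for a 'same'-padded conv layer
conv_geom <- function(in_dim, k, s) {
  h <- in_dim[1]; w <- in_dim[2]; C <- in_dim[3]
  oh <- conv_out_len(h, s[1]); ow <- conv_out_len(w, s[2])
  ph <- max((oh - 1L) * s[1] + k[1] - h, 0L)
  pw <- max((ow - 1L) * s[2] + k[2] - w, 0L)
  pt <- ph %/% 2L; pl <- pw %/% 2L
  hp <- h + ph; wp <- w + pw
  P <- oh * ow
  ki <- rep(seq_len(k[1]), times = k[2] * C)
  kj <- rep(rep(seq_len(k[2]), each = k[1]), times = C)
  kc <- rep(seq_len(C), each = k[1] * k[2])
  io <- rep(seq_len(oh), times = ow)
  jo <- rep(seq_len(ow), each = oh)
  i0 <- (io - 1L) * s[1]
  j0 <- (jo - 1L) * s[2]
  idx <- outer(ki + (kj - 1L) * hp + (kc - 1L) * hp * wp,
               i0 + j0 * hp, `+`)
  list(oh = oh, ow = ow, hp = hp, wp = wp, pt = pt, pl = pl, P = P,
       idx = idx)
}

gather_cols <- function(xp, idx, block, N) {
  offs <- (seq_len(N) - 1L) * block
  full <- rep(as.vector(idx), times = N) +
    rep(offs, each = length(idx))
  matrix(xp[full], nrow = nrow(idx))
}

conv_forward <- function(layer, x, train = FALSE) {
  g <- layer$geom
  d <- dim(x); N <- d[4]
  xp <- array(0, c(g$hp, g$wp, d[3], N))
  xp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , ] <- x
  ## im2col as one sparse gather: (khkwC*P) x N, then khkwC x (P*N)
  dim(xp) <- c(g$hp * g$wp * d[3], N)
  cols <- as.matrix(layer$gather %*% xp)
  dim(cols) <- c(length(g$idx) %/% g$P, g$P * N)
  y <- layer$W %*% cols + layer$b
  dim(y) <- c(nrow(layer$W), g$oh, g$ow, N)
  out <- aperm(y, c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, in_dim = d))
}

conv_backward <- function(layer, dy, cache, need_dx = TRUE) {
  g <- layer$geom
  d <- cache$in_dim; N <- d[4]
  dy_mat <- aperm(dy, c(3, 1, 2, 4))
  dim(dy_mat) <- c(dim(dy)[3], g$P * N)
  dW <- dy_mat %*% t(cache$cols)
  db <- rowSums(dy_mat)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dcols <- crossprod(layer$W, dy_mat)
  dim(dcols) <- c(length(g$idx), N)
  dxp <- as.matrix(Matrix::crossprod(layer$gather, dcols))
  dim(dxp) <- c(g$hp, g$wp, d[3], N)
  dx <- dxp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

pool_geom <- function(in_dim) {
  h <- in_dim[1]; w <- in_dim[2]
  oh <- pool_out_len(h); ow <- pool_out_len(w)
  io <- rep(seq_len(oh), times = ow)
  jo <- rep(seq_len(ow), each = oh)
  i0 <- (io - 1L) * 2L
  j0 <- (jo - 1L) * 2L
  corner <- c(0L, 1L, h, h + 1L)
  idx <- outer(corner, i0 + j0 * h, `+`) + 1L
  list(oh = oh, ow = ow, P = oh * ow, idx = idx)
}

pool_forward <- function(layer, x) {
  g <- layer$geom
  d <- dim(x); C <- d[3]; N <- d[4]
  cols <- gather_cols(x, g$idx, d[1] * d[2], C * N)
  amax <- max.col(t(cols), ties.method = "first")
  vals <- cols[cbind(amax, seq_along(amax))]
  out <- array(vals, c(g$oh, g$ow, C, N))
  list(out = out, cache = list(amax = amax, in_dim = d))
}

pool_backward <- function(layer, dy, cache) {
  g <- layer$geom
  d <- cache$in_dim; C <- d[3]; N <- d[4]
  block <- d[1] * d[2]
  offs <- rep((seq_len(C * N) - 1L) * block, each = g$P)
  pos <- rep(seq_len(g$P), times = C * N)
  target <- g$idx[cbind(cache$amax, pos)] + offs
  dx <- numeric(block * C * N)
  dx[target] <- as.vector(dy)
  dim(dx) <- d
  list(dx = dx)
}

#' Build an untrained CNN
#'
#' Constructs the layer graph for a `height x width` single-plane input,
#' checking that every spatial dimension survives the stride/pool chain,
#' and initialises weights (He-normal, seeded).
#'
#' @param input_shape `c(height, width)` of the feature-map window.
#' @param config A [cnn_config()].
#' @return A `cnn_model` list with `layers`, `shapes` (per-layer output
#'   dims), `n_params`, `config`.
#' @export
build_model <- function(input_shape, config = cnn_config()) {
  set.seed(as.integer(config$seed))
  dim_cur <- c(as.integer(input_shape[1]), as.integer(input_shape[2]), 1L)
  layers <- list()
  shapes <- list(input = dim_cur)
  for (i in seq_along(config$conv)) {
    cv <- config$conv[[i]]
    g <- conv_geom(dim_cur, as.integer(cv$k), as.integer(cv$stride))
    fan_in <- prod(cv$k) * dim_cur[3]
    W <- matrix(stats::rnorm(cv$filters * fan_in) * sqrt(2 / fan_in),
                cv$filters, fan_in)
    gather <- Matrix::sparseMatrix(
      i = seq_along(g$idx), j = as.vector(g$idx), x = 1,
      dims = c(length(g$idx), g$hp * g$wp * dim_cur[3]))
    layers[[length(layers) + 1L]] <-
      list(type = "conv", W = W, b = numeric(cv$filters), geom = g,
           gather = gather)
    dim_cur <- c(g$oh, g$ow, cv$filters)
    shapes[[paste0("conv", i)]] <- dim_cur
    if (i %in% config$pool_after) {
      if (pool_out_len(dim_cur[1]) < 1L || pool_out_len(dim_cur[2]) < 1L) {
        stop(sprintf(paste0("input too small: conv%d output %dx%d cannot ",
                            "be 2x2 max-pooled; use a larger window"),
                     i, dim_cur[1], dim_cur[2]))
      }
      g2 <- pool_geom(dim_cur)
      layers[[length(layers) + 1L]] <- list(type = "pool", geom = g2)
      dim_cur <- c(g2$oh, g2$ow, dim_cur[3])
      shapes[[paste0("pool", i)]] <- dim_cur
    }
    layers[[length(layers) + 1L]] <- list(type = "relu")
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  feat <- prod(dim_cur)
  shapes[["flatten"]] <- feat
  for (j in seq_along(config$dense)) {
    out <- as.integer(config$dense[j])
    W <- matrix(stats::rnorm(out * feat) * sqrt(2 / feat), out, feat)
    layers[[length(layers) + 1L]] <-
      list(type = "dense", W = W, b = numeric(out))
    shapes[[paste0("dense", j)]] <- out
    if (j < length(config$dense)) {
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (j <= 2 && config$dropout > 0) {
        layers[[length(layers) + 1L]] <-
          list(type = "dropout", rate = config$dropout)
      }
    }
    feat <- out
  }
  n_params <- sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  structure(list(layers = layers, input_shape = input_shape,
                 shapes = shapes, n_params = n_params, config = config),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %dx%d, %d layers, %d parameters\n",
              x$input_shape[1], x$input_shape[2], length(x$layers),
              x$n_params))
  invisible(x)
}

#' Trainable parameter count of a model
#' @param model A [build_model()] result.
#' @return Integer parameter count.
#' @export
count_params <- function(model) model$n_params

model_forward <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(l, x, train)
      x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "pool") {
      r <- pool_forward(l, x)
      x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(x))
      dim(x) <- c(prod(dim(x)[1:3]), dim(x)[4])
    } else if (l$type == "dense") {
      caches[[i]] <- list(xin = x)
      x <- l$W %*% x + l$b
    } else if (l$type == "dropout") {
      if (train) {
        mask <- matrix(stats::rbinom(length(x), 1, 1 - l$rate),
                       nrow(x), ncol(x)) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    }
  }
  list(logits = x, caches = caches)
}

softmax_probs <- function(logits) {
  z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(e), ncol(e), byrow = TRUE)
}

model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dx <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(dW = dx %*% t(caches[[i]]$xin), db = rowSums(dx))
      dx <- crossprod(l$W, dx)
    } else if (l$type == "relu") {
      dx <- dx * caches[[i]]$mask
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) dx <- dx * caches[[i]]$mask
    } else if (l$type == "flatten") {
      dim(dx) <- caches[[i]]$in_dim
    } else if (l$type == "pool") {
      dx <- pool_backward(l, dx, caches[[i]])$dx
    } else if (l$type == "conv") {
      r <- conv_backward(l, dx, caches[[i]], need_dx = i > 1L)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dx <- r$dx
    }
  }
  grads
}

## cross-entropy loss and gradient for labels y in {0,1}
## (class order in logits: row 1 = IIL/0, row 2 = PIL/1)
ce_loss_grad <- function(logits, y) {
  N <- ncol(logits)
  p <- softmax_probs(logits)
  iy <- y + 1L
  eps <- 1e-12
  loss <- -mean(log(p[cbind(iy, seq_len(N))] + eps))
  Y <- matrix(0, 2, N)
  Y[cbind(iy, seq_len(N))] <- 1
  list(loss = loss, dlogits = (p - Y) / N, probs = p)
}

#' Early-stopping rule on a validation-error history
#'
#' Training halts at the first epoch after which the validation error rate
#' has risen for `patience` consecutive epochs, or at `max_epochs`,
#' whichever comes first.
#'
#' @param val_errors Numeric vector of per-epoch validation error rates.
#' @param patience Consecutive-rise count that triggers the stop.
#' @param max_epochs Epoch cap.
#' @return The stopping epoch implied by the history.
#' @export
early_stopping_epoch <- function(val_errors, patience = 10L,
                                 max_epochs = 150L) {
  consec <- 0L
  n <- min(length(val_errors), max_epochs)
  for (e in seq_len(n)) {
    if (e > 1L && val_errors[e] > val_errors[e - 1L]) {
      consec <- consec + 1L
    } else {
      consec <- 0L
    }
    if (consec >= patience) return(e)
  }
  n
}

#' Train a CNN with Adam and early stopping
#'
#' @param model An untrained [build_model()] result.
#' @param train,val Lists with `x` (4-d array `h x w x 1 x n`) and `y`
#'   (integer 0/1 labels); the two sets must be disjoint and the training
#'   set must contain both classes.
#' @param config Optional override of the model's [cnn_config()].
#' @return A `trained_classifier` list: the fitted `model` (weights from
#'   the best-validation epoch), `history` (per-epoch train loss/error and
#'   validation error), `stopped_epoch`, `best_epoch`.
#' @export
train_cnn <- function(model, train, val, config = NULL) {
  if (is.null(config)) config <- model$config
  if (length(unique(train$y)) < 2L) {
    stop("training set must contain both classes")
  }
  set.seed(as.integer(config$seed) + 1L)
  N <- dim(train$x)[4]
  adam <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (!is.null(l$W)) {
      adam[[i]] <- list(mW = l$W * 0, vW = l$W * 0,
                        mb = l$b * 0, vb = l$b * 0)
    }
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_error = numeric(), val_error = numeric())
  best <- list(err = Inf, layers = model$layers, epoch = 0L)
  consec <- 0L
  prev_val <- NULL
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_err <- 0
    starts <- seq(1L, N, by = config$batch)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch - 1L, N)]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[idx]
      fw <- model_forward(model, xb, train = TRUE)
      lg <- ce_loss_grad(fw$logits, yb)
      grads <- model_backward(model, fw$caches, lg$dlogits)
      t_step <- t_step + 1L
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]]) || is.null(grads[[i]]$dW)) next
        a <- adam[[i]]
        a$mW <- b1 * a$mW + (1 - b1) * grads[[i]]$dW
        a$vW <- b2 * a$vW + (1 - b2) * grads[[i]]$dW^2
        a$mb <- b1 * a$mb + (1 - b1) * grads[[i]]$db
        a$vb <- b2 * a$vb + (1 - b2) * grads[[i]]$db^2
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        model$layers[[i]]$W <- model$layers[[i]]$W -
          config$lr * (a$mW / corr1) / (sqrt(a$vW / corr2) + eps)
        model$layers[[i]]$b <- model$layers[[i]]$b -
          config$lr * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
        adam[[i]] <- a
      }
      pred <- max.col(t(lg$probs)) - 1L
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_err <- ep_err + sum(pred != yb)
    }
    val_probs <- predict_proba(model, val$x)
    val_pred <- as.integer(val_probs[, "PIL"] > 0.5)
    val_err <- mean(val_pred != val$y)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / N,
                                   train_error = ep_err / N,
                                   val_error = val_err))
    if (val_err < best$err) {
      best <- list(err = val_err, layers = model$layers, epoch = epoch)
    }
    if (!is.null(prev_val) && val_err > prev_val) {
      consec <- consec + 1L
    } else {
      consec <- 0L
    }
    prev_val <- val_err
    if (consec >= config$patience) { stopped <- epoch; break }
    stopped <- epoch
  }
  model$layers <- best$layers
  structure(list(model = model, history = hist, stopped_epoch = stopped,
                 best_epoch = best$epoch, config = config),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> stopped at epoch %d (best %d, val error %.3f)\n",
              x$stopped_epoch, x$best_epoch,
              x$history$val_error[x$best_epoch]))
  invisible(x)
}

#' Class probabilities for feature-map windows
#'
#' Inference forward pass (dropout disabled, deterministic).
#'
#' @param model A `cnn_model` or `trained_classifier`.
#' @param x 4-d array `h x w x 1 x n` of windows.
#' @return An `n x 2` matrix with columns `IIL`, `PIL`; rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  if (inherits(model, "trained_classifier")) model <- model$model
  if (length(dim(x)) != 4L ||
      any(dim(x)[1:2] != model$input_shape[1:2])) {
    stop("window shape does not match the model's input shape")
  }
  p <- softmax_probs(model_forward(model, x, train = FALSE)$logits)
  out <- t(p)
  colnames(out) <- c("IIL", "PIL")
  out
}

#' Ablation variants of the pipeline
#'
#' `no_multiresolution` replaces the multiresolution per-band features
#' with raw-segment full-band periodogram features (a single band row, no
#' adaptive filtering); `no_subband_voting` fuses the per-band streams by
#' probability averaging instead of majority vote; `shallow` drops the
#' third conv layer.
#'
#' @param name One of `"no_multiresolution"`, `"no_subband_voting"`,
#'   `"shallow"`.
#' @return A list of pipeline-config overrides.
#' @export
ablation_variant <- function(name) {
  switch(name,
    no_multiresolution = list(variant = name, fb_only = TRUE,
                              mraf = FALSE),
    no_subband_voting = list(variant = name, fusion = "average"),
    shallow = list(variant = name, drop_conv3 = TRUE),
    stop("unknown ablation variant: ", name)
  )
}

#' @rdname ablation_variant
#' @param config A [cnn_config()].
#' @export
shallow_config <- function(config = cnn_config()) {
  config$conv <- config$conv[1:2]
  config
}
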