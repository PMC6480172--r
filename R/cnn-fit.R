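#' Training configuration
#'
#' Optimization hyperparameters for [cnn_fit()]. Defaults: Adam with learning
#' rate 1e-3, categorical cross-entropy, batch size 32, at most 100 epochs,
#' early stopping after 10 epochs without inner-validation improvement. Batch
#' normalization requires batches of at least 2 samples; a trailing 1-sample
#' mini-batch is dropped.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param loss only `"categorical_crossentropy"` is implemented.
#' @param batch_size mini-batch size (>= 2).
#' @param max_epochs maximum number of epochs (>= 1).
#' @param early_stop_patience epochs without validation-loss improvement before
#'   stopping; the best-epoch weights are restored.
#' @param val_fraction fraction of the training data reserved for epoch-wise
#'   validation when no explicit validation set is passed.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and epsilon.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         loss = "categorical_crossentropy",
                         batch_size = 32, max_epochs = 100,
                         early_stop_patience = 10, val_fraction = 0.1,
                         seed = 1, bn_momentum = 0.9,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(identical(optimizer, "adam"),
            identical(loss, "categorical_crossentropy"),
            batch_size >= 2, max_epochs >= 1, early_stop_patience >= 0,
            val_fraction >= 0, val_fraction < 1,
            bn_momentum >= 0, bn_momentum < 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 loss = loss, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 bn_momentum = bn_momentum, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps),
            class = "train_config")
}

# ---- parameter initialization (Glorot-uniform weights, zero biases) ---------

init_params <- function(spec) {
  F <- spec$filters_per_layer
  blocks <- vector("list", spec$n_blocks)
  c_in <- 1L
  for (r in seq_len(spec$n_blocks)) {
    k <- spec$filter_lengths[r]
    lim <- sqrt(6 / (k * c_in + k * F))
    blocks[[r]] <- list(
      W = matrix(runif(k * c_in * F, -lim, lim), k * c_in, F),
      b = numeric(F),
      gamma = rep(1, F), beta = numeric(F),
      # EMA of batch statistics with bias correction; bn_n counts updates
      run_mean = numeric(F), run_var = numeric(F), bn_n = 0L,
      k = k, c_in = c_in)
    c_in <- F
  }
  lim <- sqrt(6 / (spec$flatten_len + spec$n_classes))
  list(blocks = blocks,
       dense = list(W = matrix(runif(spec$flatten_len * spec$n_classes,
                                     -lim, lim),
                               spec$flatten_len, spec$n_classes),
                    b = numeric(spec$n_classes)))
}

# ---- forward / backward -----------------------------------------------------

# X: B x input_len matrix. Returns probs and (training) per-layer caches.
net_forward <- function(params, spec, X, training = FALSE,
                        dropout_mask = NULL, bn_momentum = 0.9) {
  B <- nrow(X)
  A <- array(t(X), dim = c(spec$input_len, B, 1L))
  caches <- if (training) vector("list", spec$n_blocks)
  for (r in seq_len(spec$n_blocks)) {
    blk <- params$blocks[[r]]
    Rl <- cpp_conv1d_fw(A, blk$W, blk$b, blk$k, TRUE) # conv + ReLU fused
    if (training) {
      st <- cpp_bn_stats(Rl)
      mu <- st$mu; v <- st$v # biased batch variance
      invstd <- 1 / sqrt(v + spec$bn_epsilon)
      params$blocks[[r]]$run_mean <- bn_momentum * blk$run_mean +
        (1 - bn_momentum) * mu
      params$blocks[[r]]$run_var <- bn_momentum * blk$run_var +
        (1 - bn_momentum) * v
      params$blocks[[r]]$bn_n <- blk$bn_n + 1L
      params$blocks[[r]]$bn_momentum <- bn_momentum
    } else {
      # debias the exponential moving averages (zero-initialized)
      if (!is.null(blk$bn_momentum)) bn_momentum <- blk$bn_momentum
      corr <- 1 - bn_momentum^blk$bn_n
      if (blk$bn_n > 0L) {
        mu <- blk$run_mean / corr
        v <- blk$run_var / corr
      } else {
        mu <- numeric(spec$filters_per_layer)
        v <- rep(1, spec$filters_per_layer)
      }
      invstd <- 1 / sqrt(v + spec$bn_epsilon)
    }
    Y <- cpp_bn_apply(Rl, mu, invstd, blk$gamma, blk$beta)
    P <- if (spec$pool_after_block[r]) cpp_maxpool_fw(Y) else Y
    if (training)
      caches[[r]] <- list(A_in = A, R = Rl, mu = mu, invstd = invstd,
                          bn_out = Y)
    A <- P
  }
  Lf <- dim(A)[1]; Fc <- dim(A)[3]
  Fl <- aperm(A, c(1, 3, 2)); dim(Fl) <- c(Lf * Fc, B)
  Fmat <- t(Fl)
  D <- if (training && !is.null(dropout_mask)) Fmat * dropout_mask else Fmat
  logits <- D %*% params$dense$W +
    rep(params$dense$b, each = B)
  probs <- softmax(logits)
  list(probs = probs, caches = caches, Fmat = D,
       flat_dims = c(Lf, Fc), params = params)
}

# y_idx: integer class indices (1-based). Returns gradients matching params.
net_backward <- function(params, spec, fw, y_idx, dropout_mask = NULL) {
  probs <- fw$probs
  B <- nrow(probs)
  dLogits <- probs
  dLogits[cbind(seq_len(B), y_idx)] <- dLogits[cbind(seq_len(B), y_idx)] - 1
  dLogits <- dLogits / B
  g_dense <- list(W = crossprod(fw$Fmat, dLogits), b = colSums(dLogits))
  dD <- tcrossprod(dLogits, params$dense$W)
  if (!is.null(dropout_mask)) dD <- dD * dropout_mask
  Lf <- fw$flat_dims[1]; Fc <- fw$flat_dims[2]
  dFl <- t(dD); dim(dFl) <- c(Lf, Fc, B)
  dA <- aperm(dFl, c(1, 3, 2))

  g_blocks <- vector("list", spec$n_blocks)
  for (r in rev(seq_len(spec$n_blocks))) {
    blk <- params$blocks[[r]]
    cc <- fw$caches[[r]]
    dY <- if (spec$pool_after_block[r]) cpp_maxpool_bw(cc$bn_out, dA) else dA
    bn <- cpp_bn_relu_bw(cc$R, dY, cc$mu, cc$invstd, blk$gamma)
    bw <- cpp_conv1d_bw(cc$A_in, blk$W, bn$dR, blk$k)
    g_blocks[[r]] <- list(W = bw$dW, b = as.numeric(bw$db),
                          gamma = as.numeric(bn$dgamma),
                          beta = as.numeric(bn$dbeta))
    dA <- bw$dA
  }
  list(blocks = g_blocks, dense = g_dense)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(blocks = lapply(params$blocks, function(b)
                  zero_like(b[c("W", "b", "gamma", "beta")])),
                dense = zero_like(params$dense)),
       v = list(blocks = lapply(params$blocks, function(b)
                  zero_like(b[c("W", "b", "gamma", "beta")])),
                dense = zero_like(params$dense)),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - cfg$learning_rate * (m / corr1) /
      (sqrt(v / corr2) + cfg$adam_eps)
    list(p = p, m = m, v = v)
  }
  for (r in seq_along(params$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(params$blocks[[r]][[nm]], grads$blocks[[r]][[nm]],
               state$m$blocks[[r]][[nm]], state$v$blocks[[r]][[nm]])
      params$blocks[[r]][[nm]] <- u$p
      state$m$blocks[[r]][[nm]] <- u$m
      state$v$blocks[[r]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(params$dense[[nm]], grads$dense[[nm]],
             state$m$dense[[nm]], state$v$dense[[nm]])
    params$dense[[nm]] <- u$p
    state$m$dense[[nm]] <- u$m
    state$v$dense[[nm]] <- u$v
  }
  list(params = params, state = state)
}

# ---- loss helpers -----------------------------------------------------------

xent_loss <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

batched_probs <- function(params, spec, X, batch = 256L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    out[i:j, ] <- net_forward(params, spec,
                              X[i:j, , drop = FALSE], training = FALSE)$probs
    i <- j + 1L
  }
  out
}

# ---- the fitting function ---------------------------------------------------

#' Fit a 1D-CNN classifier
#'
#' Trains the network described by a [cnn_spec()] on z-scored segments by
#' mini-batch backpropagation (Adam, categorical cross-entropy). An inner
#' validation split monitors the loss each epoch for early stopping; the
#' weights of the best validation epoch are restored. Fully seeded: the same
#' `(spec, data, config)` reproduce the identical training history.
#'
#' @param spec a [cnn_spec()]; `spec$input_len` must equal `ncol(x)`.
#' @param x numeric matrix of training segments, one per row.
#' @param y factor (or vector coercible to factor) of segment labels; at least
#'   two classes, and the number of levels must equal `spec$n_classes`.
#' @param val_x,val_y optional explicit validation set; when omitted,
#'   `config$val_fraction` of the training data is held out (stratified).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `cecg_cnn`: fields `spec`, `params` (learned
#'   weights), `label_map` (class levels in output order), `config`,
#'   `history` (per-epoch data frame), `train_seed`, `best_epoch`.
#' @seealso [predict.cecg_cnn()], [evaluate()], [cross_validate()]
#' @export
cnn_fit <- function(spec, x, y, val_x = NULL, val_y = NULL,
                    config = train_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "cnn_spec"), is.matrix(x))
  if (ncol(x) != spec$input_len)
    stop_cecg(sprintf("segments have %d samples but spec$input_len is %d",
                      ncol(x), spec$input_len), "cecg_input_error")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  labels <- levels(y)
  if (length(labels) < 2)
    stop_cecg("training data contain a single class", "cecg_config_error")
  if (length(labels) != spec$n_classes)
    stop_cecg(sprintf("%d classes in labels but spec$n_classes is %d",
                      length(labels), spec$n_classes), "cecg_config_error")
  if (nrow(x) != length(y))
    stop_cecg("nrow(x) must equal length(y)", "cecg_config_error")

  with_seed(config$seed, {
    if (is.null(val_x) && config$val_fraction > 0) {
      vi <- unlist(lapply(split(seq_along(y), y), function(ii) {
        nv <- max(1L, round(length(ii) * config$val_fraction))
        sample(ii, nv)
      }), use.names = FALSE)
      val_x <- x[vi, , drop = FALSE]; val_y <- y[vi]
      x <- x[-vi, , drop = FALSE]; y <- y[-vi]
    }
    has_val <- !is.null(val_x) && nrow(val_x) > 0
    if (has_val) {
      val_y <- factor(val_y, levels = labels)
      val_idx <- as.integer(val_y)
    }
    y_idx <- as.integer(y)
    n <- nrow(x)

    params <- init_params(spec)
    state <- adam_init(params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), val_loss = numeric(0),
                       val_acc = numeric(0))
    best <- list(loss = Inf, params = params, epoch = 0L)
    stale <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      i <- 1L
      ep_loss <- 0; ep_hits <- 0L; ep_n <- 0L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        if (j - i < 1L) break # BN needs >= 2 samples
        bi <- ord[i:j]
        Xb <- x[bi, , drop = FALSE]
        mask <- if (spec$dropout_rate > 0)
          matrix(rbinom(length(bi) * spec$flatten_len, 1L,
                        1 - spec$dropout_rate),
                 length(bi), spec$flatten_len) / (1 - spec$dropout_rate)
        fw <- net_forward(params, spec, Xb, training = TRUE,
                          dropout_mask = mask,
                          bn_momentum = config$bn_momentum)
        params <- fw$params # running BN stats updated
        loss <- xent_loss(fw$probs, y_idx[bi])
        if (!is.finite(loss))
          stop_cecg("training diverged: non-finite loss",
                    "cecg_training_divergence", history = hist)
        grads <- net_backward(params, spec, fw, y_idx[bi], mask)
        st <- adam_step(params, grads, state, config)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + loss * length(bi)
        ep_hits <- ep_hits + sum(max.col(fw$probs) == y_idx[bi])
        ep_n <- ep_n + length(bi)
        i <- j + 1L
      }
      train_loss <- ep_loss / ep_n
      train_acc <- ep_hits / ep_n
      if (has_val) {
        vp <- batched_probs(params, spec, val_x)
        val_loss <- xent_loss(vp, val_idx)
        val_acc <- mean(max.col(vp) == val_idx)
      } else {
        val_loss <- train_loss; val_acc <- train_acc
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     train_acc = train_acc,
                                     val_loss = val_loss, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, train_loss, train_acc, val_loss, val_acc))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale > config$early_stop_patience) break
      }
    }

    structure(list(spec = spec, params = best$params, label_map = labels,
                   config = config, history = hist,
                   train_seed = config$seed, best_epoch = best$epoch),
              class = "cecg_cnn")
  })
}

#' Predict quality or position labels for segments
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics, dropout off).
#'
#' @param object a fitted [cnn_fit()] model.
#' @param x matrix of z-scored segments, one per row, with
#'   `object$spec$input_len` columns.
#' @param type `"class"` for a factor of predicted labels, `"prob"` for the
#'   n x n_classes matrix of softmax probabilities (columns named by
#'   `label_map`).
#' @param ... unused.
#' @return factor or probability matrix.
#' @export
predict.cecg_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$spec$input_len)
    stop_cecg(sprintf("segments have %d samples but the model expects %d",
                      ncol(x), object$spec$input_len), "cecg_input_error")
  probs <- batched_probs(object$params, object$spec, x)
  colnames(probs) <- object$label_map
  if (type == "prob") return(probs)
  factor(object$label_map[max.col(probs, ties.method = "first")],
         levels = object$label_map)
}

#' @export
print.cecg_cnn <- function(x, ...) {
  cat(sprintf("cECG 1D-CNN classifier (%s): %d blocks, input %d samples\n",
              paste(x$label_map, collapse = "/"), x$spec$n_blocks,
              x$spec$input_len))
  h <- x$history
  cat(sprintf("  trained %d epochs (best epoch %d), final val loss %.4f, val acc %.3f\n",
              nrow(h), x$best_epoch, h$val_loss[x$best_epoch],
              h$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.cecg_cnn <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' @export
coef.cecg_cnn <- function(object, ...) object$params

#' Plot the training history of a fitted classifier
#' @param x a `cecg_cnn` model.
#' @param ... passed to [plot()].
#' @export
plot.cecg_cnn <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  abline(v = x$best_epoch, col = "grey60", lty = 3)
  legend("topright", legend = c("train", "validation"), lty = c(1, 2),
         bty = "n")
  invisible(x)
}

#' Persist / restore a fitted model
#'
#' The weights are stored with [saveRDS()]; the architecture spec and label map
#' are additionally written as a JSON sidecar so a model directory is
#' self-describing.
#'
#' @param model a `cecg_cnn`.
#' @param path `.rds` path for the weights.
#' @return invisibly, the paths written.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cecg_cnn"))
  saveRDS(model, path)
  js <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(list(spec = unclass(model$spec),
                            label_map = model$label_map,
                            train_seed = model$train_seed),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(rds = path, json = js))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cecg_cnn"))
  m
}
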