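# Architecture assembly, forward/backward passes and the SGD loop.

NN_ARCHS <- c("cnn", "cnn_lstm", "attention", "linear")

# shape trace of the CNN: L -> conv(same) -> pool2 -> ... ; used both to
# build layers and to reject too-short inputs
cnnShapeTrace <- function(L) {
  trace <- c(conv1 = L, conv2 = L, pool1 = L %/% 2L)
  trace <- c(trace, conv3 = unname(trace["pool1"]),
             conv4 = unname(trace["pool1"]),
             pool2 = unname(trace["pool1"]) %/% 2L)
  trace
}

#' Build an untrained sequence-to-activity network
#'
#' Architectures follow the fixed layer listings: the CNN is
#' conv(k=5, pad=2, 100) - ReLU - conv(5,2,200) - ReLU - maxpool(2) -
#' conv(5,2,200) - ReLU - conv(5,2,5) - ReLU - maxpool(2) - dense(1);
#' the CNN-LSTM and attention variants share the first conv/pool block and
#' differ downstream; the linear baseline is a single dense layer on the
#' flattened one-hot encoding (4L + 1 parameters).
#'
#' @param arch One of `"cnn"`, `"cnn_lstm"`, `"attention"`, `"linear"`.
#' @param L Input sequence length (>= 8 for pooled architectures so two
#'   halvings leave at least one position).
#' @param seed Integer seed for weight initialisation (Glorot uniform).
#' @return A model object (list) for [nnForward()] / [nnTrain()].
#' @export
nnBuild <- function(arch = NN_ARCHS, L = 31L, seed = 1L) {
  arch <- match.arg(arch)
  if (arch != "linear") {
    tr <- cnnShapeTrace(L)
    if (any(tr < 1L))
      stop(sprintf("L = %d is too short: layer '%s' would have length %d",
                   L, names(tr)[which(tr < 1L)[1L]], min(tr)))
    if (L < 8L) stop("pooled architectures require L >= 8")
  }
  withSeed(seed, {
    layers <- switch(arch,
      cnn = {
        tr <- cnnShapeTrace(L)
        list(conv1 = .layerConv(5L, 2L, 4L, 100L),
             conv2 = .layerConv(5L, 2L, 100L, 200L),
             conv3 = .layerConv(5L, 2L, 200L, 200L),
             conv4 = .layerConv(5L, 2L, 200L, 5L),
             dense = .layerDense(unname(tr["pool2"]) * 5L, 1L))
      },
      cnn_lstm = list(
        conv1 = .layerConv(5L, 2L, 4L, 100L),
        lstm1 = .layerLSTM(100L, 200L, returnSeq = TRUE),
        lstm2 = .layerLSTM(200L, 100L, returnSeq = FALSE),
        dense1 = .layerDense(100L, 1024L, act = "relu"),
        dense2 = .layerDense(1024L, 1L)),
      attention = list(
        conv1 = .layerConv(5L, 2L, 4L, 100L),
        qk = .layerTimeDense(100L, 64L),
        v = .layerTimeDense(100L, 64L),
        dense1 = .layerDense((L %/% 2L) * 64L, 1024L, act = "relu"),
        dense2 = .layerDense(1024L, 1L)),
      linear = list(dense = .layerDense(4L * L, 1L)))
    list(arch = arch, L = L, layers = layers, seed = seed)
  })
}

#' Number of trainable parameters of a model
#' @param model An `orthoNN` model.
#' @return Integer parameter count.
#' @export
nnCountParams <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(l[names(l) %in% c("W", "b", "Wx", "Wh")],
               length, integer(1)))
  }, numeric(1)))
}

# forward pass; returns prediction vector, caches for backward, and
# post-ReLU conv feature maps when keepFeatures = TRUE
nnForward <- function(model, X, keepFeatures = FALSE) {
  ly <- model$layers
  cc <- list()
  feats <- list()
  out <- switch(model$arch,
    cnn = {
      h <- .fwdConv(ly$conv1, X); cc$conv1 <- h$cache
      r <- .fwdRelu(h$out); cc$relu1 <- r$cache
      if (keepFeatures) feats$conv1 <- r$out
      h <- .fwdConv(ly$conv2, r$out); cc$conv2 <- h$cache
      r <- .fwdRelu(h$out); cc$relu2 <- r$cache
      if (keepFeatures) feats$conv2 <- r$out
      p <- .fwdPool2(r$out); cc$pool1 <- p$cache
      h <- .fwdConv(ly$conv3, p$out); cc$conv3 <- h$cache
      r <- .fwdRelu(h$out); cc$relu3 <- r$cache
      if (keepFeatures) feats$conv3 <- r$out
      h <- .fwdConv(ly$conv4, r$out); cc$conv4 <- h$cache
      r <- .fwdRelu(h$out); cc$relu4 <- r$cache
      feats$conv4 <- r$out
      p <- .fwdPool2(r$out); cc$pool2 <- p$cache
      d <- dim(p$out)
      flat <- matrix(p$out, d[1L], d[2L] * d[3L])
      cc$flatDim <- d
      f <- .fwdDense(ly$dense, flat); cc$dense <- f$cache
      f$out[, 1L]
    },
    cnn_lstm = {
      h <- .fwdConv(ly$conv1, X); cc$conv1 <- h$cache
      r <- .fwdRelu(h$out); cc$relu1 <- r$cache
      if (keepFeatures) feats$conv1 <- r$out
      p <- .fwdPool2(r$out); cc$pool1 <- p$cache
      l1 <- .fwdLSTM(ly$lstm1, p$out); cc$lstm1 <- l1$cache
      l2 <- .fwdLSTM(ly$lstm2, l1$out); cc$lstm2 <- l2$cache
      f1 <- .fwdDense(ly$dense1, l2$out); cc$dense1 <- f1$cache
      f2 <- .fwdDense(ly$dense2, f1$out); cc$dense2 <- f2$cache
      f2$out[, 1L]
    },
    attention = {
      h <- .fwdConv(ly$conv1, X); cc$conv1 <- h$cache
      r <- .fwdRelu(h$out); cc$relu1 <- r$cache
      if (keepFeatures) feats$conv1 <- r$out
      p <- .fwdPool2(r$out); cc$pool1 <- p$cache
      qk <- .fwdTimeDense(ly$qk, p$out); cc$qk <- qk$cache
      v <- .fwdTimeDense(ly$v, p$out); cc$v <- v$cache
      at <- .fwdAttention(list(qk = qk$out, v = v$out)); cc$att <- at$cache
      d <- dim(at$out)
      flat <- matrix(at$out, d[1L], d[2L] * d[3L])
      cc$flatDim <- d
      f1 <- .fwdDense(ly$dense1, flat); cc$dense1 <- f1$cache
      f2 <- .fwdDense(ly$dense2, f1$out); cc$dense2 <- f2$cache
      f2$out[, 1L]
    },
    linear = {
      d <- dim(X)
      flat <- matrix(X, d[1L], d[2L] * d[3L])
      cc$flatDim <- d
      f <- .fwdDense(ly$dense, flat); cc$dense <- f$cache
      f$out[, 1L]
    })
  list(pred = out, cache = cc, features = feats)
}

# backward pass from d(loss)/d(pred); returns per-layer weight gradients
# and the gradient with respect to the input encoding
nnBackward <- function(model, cache, dPred) {
  ly <- model$layers
  g <- list()
  dPred <- matrix(dPred, ncol = 1L)
  dX <- switch(model$arch,
    cnn = {
      b <- .bwdDense(ly$dense, cache$dense, dPred); g$dense <- b$grads
      d <- cache$flatDim
      dp <- .bwdPool2(cache$pool2, array(b$dX, d))
      dp <- dp * cache$relu4
      b <- .bwdConv(ly$conv4, cache$conv4, dp); g$conv4 <- b$grads
      dp <- b$dX * cache$relu3
      b <- .bwdConv(ly$conv3, cache$conv3, dp); g$conv3 <- b$grads
      dp <- .bwdPool2(cache$pool1, b$dX)
      dp <- dp * cache$relu2
      b <- .bwdConv(ly$conv2, cache$conv2, dp); g$conv2 <- b$grads
      dp <- b$dX * cache$relu1
      b <- .bwdConv(ly$conv1, cache$conv1, dp); g$conv1 <- b$grads
      b$dX
    },
    cnn_lstm = {
      b <- .bwdDense(ly$dense2, cache$dense2, dPred); g$dense2 <- b$grads
      b <- .bwdDense(ly$dense1, cache$dense1, b$dX); g$dense1 <- b$grads
      l <- .bwdLSTM(ly$lstm2, cache$lstm2, b$dX); g$lstm2 <- l$grads
      l <- .bwdLSTM(ly$lstm1, cache$lstm1, l$dX); g$lstm1 <- l$grads
      dp <- .bwdPool2(cache$pool1, l$dX)
      dp <- dp * cache$relu1
      b <- .bwdConv(ly$conv1, cache$conv1, dp); g$conv1 <- b$grads
      b$dX
    },
    attention = {
      b <- .bwdDense(ly$dense2, cache$dense2, dPred); g$dense2 <- b$grads
      b <- .bwdDense(ly$dense1, cache$dense1, b$dX); g$dense1 <- b$grads
      at <- .bwdAttention(cache$att, array(b$dX, cache$flatDim))
      bq <- .bwdTimeDense(ly$qk, cache$qk, at$dqk); g$qk <- bq$grads
      bv <- .bwdTimeDense(ly$v, cache$v, at$dv); g$v <- bv$grads
      dp <- .bwdPool2(cache$pool1, bq$dX + bv$dX)
      dp <- dp * cache$relu1
      b <- .bwdConv(ly$conv1, cache$conv1, dp); g$conv1 <- b$grads
      b$dX
    },
    linear = {
      b <- .bwdDense(ly$dense, cache$dense, dPred); g$dense <- b$grads
      array(b$dX, cache$flatDim)
    })
  list(grads = g, dX = dX)
}

#' Predict network outputs for a batch of one-hot encodings
#'
#' @param model An `orthoNN` model.
#' @param X Array `[n, L, 4]`.
#' @param batch Chunk size to bound memory use.
#' @return Numeric vector of raw network outputs.
#' @export
nnPredict <- function(model, X, batch = 512L) {
  n <- dim(X)[1L]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(n, start + batch - 1L)
    out[idx] <- nnForward(model, X[idx, , , drop = FALSE])$pred
  }
  out
}

#' Train a network by stochastic gradient descent
#'
#' The optimiser is plain SGD with momentum 0.9 and learning-rate decay
#' `lr_t = lr / (1 + decay * t)` over update steps, minimising mean squared
#' error, with best-validation-loss checkpointing: the returned weights are
#' the ones with the lowest validation MSE seen during training.
#'
#' @param model An `orthoNN` model from [nnBuild()].
#' @param X,y Training encodings `[n, L, 4]` and targets.
#' @param valX,valy Validation set used for checkpointing/early stopping.
#' @param epochs Maximum epochs.
#' @param batch Minibatch size.
#' @param lr,decay,momentum SGD hyperparameters (defaults 5e-4, 1e-6, 0.9).
#' @param patience Early-stopping patience in epochs (no improvement of
#'   validation MSE); `Inf` disables early stopping.
#' @param seed Seed controlling shuffling.
#' @return The model with trained weights and a `history` element
#'   (per-epoch train/validation MSE, best epoch).
#' @export
nnTrain <- function(model, X, y, valX, valy, epochs = 120L, batch = 32L,
                    lr = 5e-4, decay = 1e-6, momentum = 0.9,
                    patience = 15L, seed = 1L) {
  n <- dim(X)[1L]
  stopifnot(length(y) == n, dim(valX)[1L] == length(valy))
  vel <- lapply(model$layers, function(l)
    lapply(l[names(l) %in% c("W", "b", "Wx", "Wh")], function(w) w * 0))
  iter <- 0L
  bestVal <- Inf; bestLayers <- model$layers; bestEpoch <- 0L
  hist <- data.frame(epoch = integer(0), train_mse = numeric(0),
                     val_mse = numeric(0))
  wait <- 0L
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      trLoss <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(n, start + batch - 1L)]
        Xb <- X[idx, , , drop = FALSE]
        fw <- nnForward(model, Xb)
        err <- fw$pred - y[idx]
        trLoss <- trLoss + sum(err^2)
        bw <- nnBackward(model, fw$cache, 2 * err / length(idx))
        lrT <- lr / (1 + decay * iter)
        iter <- iter + 1L
        for (ln in names(bw$grads)) {
          for (wn in names(bw$grads[[ln]])) {
            vel[[ln]][[wn]] <- momentum * vel[[ln]][[wn]] -
              lrT * bw$grads[[ln]][[wn]]
            model$layers[[ln]][[wn]] <- model$layers[[ln]][[wn]] +
              vel[[ln]][[wn]]
          }
        }
      }
      valPred <- nnPredict(model, valX)
      valLoss <- mean((valPred - valy)^2)
      hist[nrow(hist) + 1L, ] <- list(ep, trLoss / n, valLoss)
      if (valLoss < bestVal - 1e-12) {
        bestVal <- valLoss; bestLayers <- model$layers; bestEpoch <- ep
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$layers <- bestLayers
  model$history <- list(log = hist, bestEpoch = bestEpoch,
                        bestValMSE = bestVal, epochsRun = nrow(hist))
  model
}
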