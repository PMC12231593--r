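# Sequence-to-activity predictors: training recipe, evaluation, learning
# curves and architecture comparison.
#
# A predictor's "role" records which activity it estimates: "orthogonal"
# models are trained on purified (induced minus uninduced) activities,
# "host" models on uninduced activities, "mixed" models on induced
# activities. Targets are modelled on a log1p scale by default (fluorescence
# noise is close to lognormal) and internally standardised; predictions are
# reported on the linear activity scale.

PREDICTOR_ROLES <- c("orthogonal", "host", "mixed")

#' @rdname TrainedPredictor-class
#' @slot model The fitted network (architecture id, layer weights, training
#'   history).
#' @slot role One of `"orthogonal"`, `"host"`, `"mixed"`.
#' @slot responseScale `"log1p"` or `"linear"`.
#' @slot yCenter,yScale Standardisation applied to the (transformed)
#'   training targets.
#' @slot split List of train/validation/test row indices.
#' @slot metrics Held-out evaluation metrics recorded at training time.
#' @export
setClass("TrainedPredictor",
  representation(model = "list", role = "character",
                 responseScale = "character", yCenter = "numeric",
                 yScale = "numeric", split = "list", metrics = "list"),
  validity = function(object) {
    if (!object@role %in% PREDICTOR_ROLES) return("unknown role")
    if (!object@responseScale %in% c("log1p", "linear"))
      return("responseScale must be 'log1p' or 'linear'")
    TRUE
  })

setMethod("show", "TrainedPredictor", function(object) {
  h <- object@model$history
  cat(sprintf("TrainedPredictor (%s, role = %s, L = %d)\n",
              object@model$arch, object@role, object@model$L))
  if (!is.null(h))
    cat(sprintf("  trained %d epochs (best %d), val MSE %.4g\n",
                h$epochsRun, h$bestEpoch, h$bestValMSE))
  if (length(object@metrics))
    cat(sprintf("  held-out R = %.3f, R^2 = %.3f (n = %d)\n",
                object@metrics$pearsonR, object@metrics$R2,
                object@metrics$nTest))
})

#' Architecture of a predictor
#' @param predictor A [TrainedPredictor-class].
#' @return Character scalar.
#' @export
predictorArch <- function(predictor) predictor@model$arch

#' Role of a predictor
#' @param predictor A [TrainedPredictor-class].
#' @return `"orthogonal"`, `"host"` or `"mixed"`.
#' @export
predictorRole <- function(predictor) predictor@role

# target column for a role
.roleTarget <- function(role) {
  switch(role, orthogonal = "purified", host = "uninduced", mixed = "induced")
}

# parse "80/10/10", "90/10", "95/5" into fractions
.parseSplit <- function(split) {
  if (is.numeric(split)) {
    fr <- split / sum(split)
  } else {
    fr <- as.numeric(strsplit(split, "/")[[1L]]) / 100
  }
  if (length(fr) == 2L) fr <- c(fr[1L], 0, fr[2L])
  if (length(fr) != 3L || abs(sum(fr) - 1) > 1e-6)
    stop("split must be like '80/10/10', '90/10' or '95/5'")
  stats::setNames(fr, c("train", "val", "test"))
}

# seeded index split; when the nominal validation fraction is 0 a tenth of
# the training rows is carved out for checkpointing only
.makeSplit <- function(n, fractions, seed) {
  withSeed(seed, {
    idx <- sample.int(n)
    nTest <- round(fractions["test"] * n)
    nVal <- round(fractions["val"] * n)
    test <- sort(idx[seq_len(nTest)])
    val <- sort(idx[nTest + seq_len(nVal)])
    train <- sort(idx[(nTest + nVal + 1L):n])
    if (length(val) == 0L) {
      k <- max(1L, round(0.1 * length(train)))
      val <- sort(train[seq_len(k)])
      train <- setdiff(train, val)
    }
    if (!length(train) || !length(test))
      stop("split leaves an empty train or test partition")
    list(train = train, val = val, test = test)
  })
}

.transformY <- function(y, scale) if (scale == "log1p") log1p(y) else y
.invTransformY <- function(z, scale) if (scale == "log1p") expm1(z) else z

#' Train a sequence-to-activity predictor
#'
#' Networks are optimised by stochastic gradient descent with learning rate
#' 0.0005, learning-rate decay 1e-6 and momentum 0.9 under mean-squared-error
#' loss, retaining the weights with the best validation loss. The
#' `"90/10"` and `"95/5"` splits have no explicit validation fraction; a
#' tenth of the training rows is then used for checkpointing only.
#'
#' @param records Activity `data.frame` (see [readActivityTable()]).
#' @param role Which activity to model: `"orthogonal"` (purified),
#'   `"host"` (uninduced) or `"mixed"` (induced).
#' @param arch Network architecture (see [nnBuild()]).
#' @param split `"80/10/10"`, `"90/10"` or `"95/5"`.
#' @param seed Seed controlling initialisation, the split and shuffling.
#' @param epochs,batch,patience Training-loop controls.
#' @param lr,decay,momentum SGD hyperparameters; defaults are the standard
#'   recipe above and there is no hyperparameter search.
#' @param responseScale `"log1p"` (default) or `"linear"` target scale.
#' @param refit95 If `TRUE`, after held-out evaluation the model is refit on
#'   95% of the data (the design-time convention: evaluation uses a held-out
#'   split, design uses a model trained on nearly all data).
#' @return A [TrainedPredictor-class].
#' @export
trainPredictor <- function(records, role = PREDICTOR_ROLES, arch = "cnn",
                           split = "80/10/10", seed = 1L, epochs = 300L,
                           batch = 32L, patience = 30L, lr = 5e-4,
                           decay = 1e-6, momentum = 0.9,
                           responseScale = c("log1p", "linear"),
                           refit95 = FALSE) {
  role <- match.arg(role)
  responseScale <- match.arg(responseScale)
  target <- records[[.roleTarget(role)]]
  if (is.null(target) || all(is.na(target)))
    stop(sprintf("records lack '%s' activities needed for role '%s'",
                 .roleTarget(role), role))
  keep <- !is.na(target)
  records <- records[keep, , drop = FALSE]
  target <- target[keep]
  if (any(target < 0)) stop("activities must be non-negative")
  X <- encodeOneHotBatch(records$sequence)
  L <- dim(X)[2L]
  yT <- .transformY(target, responseScale)
  yC <- mean(yT)
  yS <- stats::sd(yT)
  constantTarget <- !is.finite(yS) || yS < 1e-12
  if (constantTarget) yS <- 1
  z <- (yT - yC) / yS
  sp <- .makeSplit(length(z), .parseSplit(split), childSeed(seed, 1L))

  fitOne <- function(trainIdx, valIdx) {
    model <- nnBuild(arch, L = L, seed = childSeed(seed, 2L))
    if (arch == "cnn") {
      fit <- .cnnTrainCpp(X[trainIdx, , , drop = FALSE], z[trainIdx],
                          X[valIdx, , , drop = FALSE], z[valIdx],
                          model$layers, as.integer(epochs), as.integer(batch),
                          lr, decay, momentum, as.integer(patience),
                          as.integer(childSeed(seed, 3L)))
      model$layers <- fit$layers
      model$history <- list(
        log = data.frame(epoch = seq_along(fit$train_mse),
                         train_mse = fit$train_mse, val_mse = fit$val_mse),
        bestEpoch = fit$bestEpoch, bestValMSE = fit$bestValMSE,
        epochsRun = fit$epochsRun)
      model
    } else {
      nnTrain(model, X[trainIdx, , , drop = FALSE], z[trainIdx],
              X[valIdx, , , drop = FALSE], z[valIdx], epochs = epochs,
              batch = batch, lr = lr, decay = decay, momentum = momentum,
              patience = patience, seed = childSeed(seed, 3L))
    }
  }

  model <- fitOne(sp$train, sp$val)
  pred <- new("TrainedPredictor", model = model, role = role,
              responseScale = responseScale, yCenter = yC, yScale = yS,
              split = sp, metrics = list())
  ev <- evaluatePredictor(pred, records[sp$test, , drop = FALSE])
  if (constantTarget) ev$constantTarget <- TRUE
  pred@metrics <- ev
  if (refit95) {
    sp95 <- .makeSplit(length(z), .parseSplit("95/5"), childSeed(seed, 4L))
    pred@model <- fitOne(sp95$train, sp95$val)
    pred@split <- sp95
    pred@metrics$refit95 <- TRUE
  }
  pred
}

# raw model outputs (standardised transformed scale) for encodings
.predictZ <- function(predictor, X, batch = 512L) {
  if (predictor@model$arch == "cnn") {
    n <- dim(X)[1L]
    out <- numeric(n)
    for (s in seq(1L, n, by = batch)) {
      idx <- s:min(n, s + batch - 1L)
      out[idx] <- .cnnForwardCpp(X[idx, , , drop = FALSE],
                                 predictor@model$layers)$pred
    }
    out
  } else {
    nnPredict(predictor@model, X, batch = batch)
  }
}

#' Predict activities for sequences
#'
#' @param predictor A [TrainedPredictor-class].
#' @param seqs Character vector of sequences (length must match the model).
#' @return Numeric vector of predicted activities on the linear scale.
#' @export
predictActivity <- function(predictor, seqs) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  if (nchar(seqs[1L]) != predictor@model$L)
    stop("sequence length does not match the predictor")
  z <- .predictZ(predictor, encodeOneHotBatch(seqs))
  .invTransformY(z * predictor@yScale + predictor@yCenter,
                 predictor@responseScale)
}

#' Prediction and input gradient for a relaxed encoding
#'
#' Evaluates the predictor on a real-valued (relaxed) encoding matrix and
#' returns the predicted linear-scale activity together with its gradient
#' with respect to every encoding cell, the quantity driving gradient-based
#' sequence design. On a hard one-hot encoding the prediction equals
#' [predictActivity()] on the decoded sequence.
#'
#' @param predictor A [TrainedPredictor-class].
#' @param enc L x 4 numeric matrix (or `[n, L, 4]` array for a batch).
#' @return For a matrix: `list(activity, gradient)`; for an array:
#'   `list(activity (n), gradient [n, L, 4])`.
#' @export
predictRelaxed <- function(predictor, enc) {
  single <- is.matrix(enc)
  X <- if (single) array(enc, c(1L, dim(enc))) else enc
  if (length(dim(X)) != 3L || dim(X)[3L] != 4L ||
      dim(X)[2L] != predictor@model$L)
    stop("encoding must be L x 4 matching the predictor")
  res <- .relaxedWithChain(predictor, X, rep(1, dim(X)[1L]))
  if (single)
    list(activity = res$activity[1L], gradient = res$gradient[1L, , ])
  else
    list(activity = res$activity, gradient = res$gradient)
}

# activity a_i and d(sum_i w_i a_i)/dX for relaxed encodings, with the
# chain rule through the response transform; w is a per-sample weight
.relaxedWithChain <- function(predictor, X, w) {
  m <- predictor@model
  if (m$arch == "cnn") {
    fw <- .cnnForwardCpp(X, m$layers)
    zt <- fw$pred * predictor@yScale + predictor@yCenter
    act <- .invTransformY(zt, predictor@responseScale)
    chain <- if (predictor@responseScale == "log1p") exp(zt) else rep(1, length(zt))
    dPred <- w * chain * predictor@yScale
    g <- .cnnGradCpp(X, m$layers, dPred, TRUE)
    list(activity = act, gradient = g$dX)
  } else {
    fw <- nnForward(m, X)
    zt <- fw$pred * predictor@yScale + predictor@yCenter
    act <- .invTransformY(zt, predictor@responseScale)
    chain <- if (predictor@responseScale == "log1p") exp(zt) else rep(1, length(zt))
    bw <- nnBackward(m, fw$cache, w * chain * predictor@yScale)
    list(activity = act, gradient = bw$dX)
  }
}

#' Evaluate a predictor on labelled records
#'
#' Computes Pearson R, its square and the mean squared error between
#' predicted and measured activities on the linear scale. R squared here is
#' the square of the Pearson correlation (the convention used for the
#' headline accuracy figures), not the regression coefficient of
#' determination.
#'
#' @param predictor A [TrainedPredictor-class].
#' @param records Activity `data.frame` carrying the role's target column.
#' @return List with `pearsonR`, `R2`, `mse`, `nTest`.
#' @export
evaluatePredictor <- function(predictor, records) {
  target <- records[[.roleTarget(predictor@role)]]
  keep <- !is.na(target)
  if (sum(keep) < 3L) stop("need at least 3 labelled records to evaluate")
  target <- target[keep]
  pred <- predictActivity(predictor, records$sequence[keep])
  mse <- mean((pred - target)^2)
  if (stats::sd(target) < 1e-12 || stats::sd(pred) < 1e-12) {
    list(pearsonR = NA_real_, R2 = NA_real_, mse = mse, nTest = sum(keep),
         degenerate = TRUE)
  } else {
    r <- stats::cor(pred, target)
    list(pearsonR = r, R2 = r^2, mse = mse, nTest = sum(keep))
  }
}

#' Learning curve over training-set sizes
#'
#' Trains on nested subsamples of the training split against one fixed test
#' split, repeating each size with distinct derived seeds.
#'
#' @param records Activity `data.frame`.
#' @param sizes Integer vector of training-set sizes.
#' @param repeats Repetitions per size.
#' @param seed Base seed.
#' @param role,arch,epochs,patience,... Passed to [trainPredictor()]-style
#'   training on each subsample.
#' @return `data.frame` with columns `n`, `meanR2`, `sdR2`.
#' @export
learningCurve <- function(records, sizes = c(50L, 100L, 300L, 600L, 1252L),
                          repeats = 2L, seed = 1L, role = "orthogonal",
                          arch = "cnn", epochs = 150L, patience = 20L) {
  target <- records[[.roleTarget(role)]]
  keep <- !is.na(target)
  records <- records[keep, , drop = FALSE]
  n <- nrow(records)
  sp <- .makeSplit(n, .parseSplit("80/10/10"), childSeed(seed, 21L))
  sizes <- sizes[sizes <= length(sp$train)]
  res <- lapply(sizes, function(sz) {
    r2 <- vapply(seq_len(repeats), function(rep) {
      sub <- withSeed(childSeed(seed, 100L * sz + rep),
                      sample(sp$train, sz))
      subRecords <- records[c(sub, sp$val, sp$test), , drop = FALSE]
      # retrain on the subsample with the same fixed val/test rows
      nSub <- length(sub); nVal <- length(sp$val); nTest <- length(sp$test)
      p <- .trainOnIndices(subRecords, seq_len(nSub),
                           nSub + seq_len(nVal),
                           nSub + nVal + seq_len(nTest),
                           role, childSeed(seed, 200L + rep),
                           epochs, patience, arch = arch)
      p$R2
    }, numeric(1))
    data.frame(n = sz, meanR2 = mean(r2), sdR2 = stats::sd(r2))
  })
  do.call(rbind, res)
}

# train with explicit index partitions; returns held-out metrics
.trainOnIndices <- function(records, train, val, test, role, seed,
                            epochs, patience, arch = "cnn") {
  target <- records[[.roleTarget(role)]]
  X <- encodeOneHotBatch(records$sequence)
  yT <- log1p(target)
  yC <- mean(yT[train]); yS <- stats::sd(yT[train])
  if (!is.finite(yS) || yS < 1e-12) yS <- 1
  z <- (yT - yC) / yS
  model <- nnBuild(arch, L = dim(X)[2L], seed = childSeed(seed, 2L))
  if (arch == "cnn") {
    fit <- .cnnTrainCpp(X[train, , , drop = FALSE], z[train],
                        X[val, , , drop = FALSE], z[val], model$layers,
                        as.integer(epochs), 32L, 5e-4, 1e-6, 0.9,
                        as.integer(patience), as.integer(childSeed(seed, 3L)))
    model$layers <- fit$layers
  } else {
    model <- nnTrain(model, X[train, , , drop = FALSE], z[train],
                     X[val, , , drop = FALSE], z[val], epochs = epochs,
                     patience = patience, seed = childSeed(seed, 3L))
  }
  zPred <- if (arch == "cnn")
    .cnnForwardCpp(X[test, , , drop = FALSE], model$layers)$pred
  else nnPredict(model, X[test, , , drop = FALSE])
  pred <- expm1(zPred * yS + yC)
  r <- stats::cor(pred, target[test])
  list(R = r, R2 = r^2, model = model, yCenter = yC, yScale = yS)
}

#' Compare architectures on identical splits
#'
#' Trains each architecture on the same train/validation/test partitions for
#' several seeds and reports the mean and standard deviation of the held-out
#' Pearson correlation.
#'
#' @param records Activity `data.frame`.
#' @param archs Architectures to compare.
#' @param seeds Integer vector of seeds (one model per architecture per
#'   seed).
#' @param role Target activity role.
#' @param split Split specification (default `"90/10"`).
#' @param epochs,patience Training-loop controls.
#' @return `data.frame` with one row per architecture: `arch`, `meanR`,
#'   `sdR`, `nSeeds`.
#' @export
compareArchitectures <- function(records, archs = c("cnn", "cnn_lstm",
                                                    "attention", "linear"),
                                 seeds = 1:5, role = "orthogonal",
                                 split = "90/10", epochs = 150L,
                                 patience = 20L) {
  target <- records[[.roleTarget(role)]]
  records <- records[!is.na(target), , drop = FALSE]
  rows <- lapply(archs, function(a) {
    rs <- vapply(seeds, function(sd0) {
      sp <- .makeSplit(nrow(records), .parseSplit(split),
                       childSeed(sd0, 1L))
      .trainOnIndices(records, sp$train, sp$val, sp$test, role,
                      sd0, epochs, patience, arch = a)$R
    }, numeric(1))
    data.frame(arch = a, meanR = mean(rs), sdR = stats::sd(rs),
               nSeeds = length(seeds))
  })
  do.call(rbind, rows)
}
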