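# Model interpretation: activity landscapes built from penultimate-layer
# feature maps, optimization-route projection, receptive fields,
# maximal-activation kernel motifs, and motif clustering.

#' Penultimate-layer feature maps
#'
#' Returns the post-ReLU feature maps of the last convolutional layer
#' (five kernels) for a batch of sequences. These are the coordinates from
#' which activity landscapes are drawn.
#'
#' @param predictor A CNN [TrainedPredictor-class].
#' @param seqs Character vector of sequences.
#' @return Array `[n, positions, 5]`.
#' @export
penultimateFeatures <- function(predictor, seqs) {
  .convFeatures(predictor, seqs, "conv4")
}

# post-ReLU feature maps of any conv layer, chunked
.convFeatures <- function(predictor, seqs, layerName, chunk = 256L) {
  if (predictor@model$arch != "cnn")
    stop("feature maps are defined for the CNN architecture only")
  seqs <- checkDNA(seqs, sameLength = TRUE)
  n <- length(seqs)
  out <- NULL
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    f <- .cnnForwardCpp(encodeOneHotBatch(seqs[idx]),
                        predictor@model$layers, TRUE)[[layerName]]
    if (is.null(out))
      out <- array(0, c(n, dim(f)[2L], dim(f)[3L]))
    out[idx, , ] <- f
  }
  out
}

#' @rdname LandscapeProjection-class
#' @slot kind `"host"`, `"mixed"` or `"orthogonal"`.
#' @slot kernels The two kernel indices used as x and y axes.
#' @slot points `data.frame` with `kx`, `ky`, `z` per input sequence.
#' @slot grid List with `x`, `y` axis vectors and `z` matrix (kernel-
#'   smoothed activity surface).
#' @slot bandwidth Smoothing bandwidths used (fraction of axis range 0.05).
#' @slot predictor The predictor that produced the projection (needed to
#'   project new sequences, e.g. optimization routes).
#' @export
setClass("LandscapeProjection",
  representation(kind = "character", kernels = "integer",
                 points = "data.frame", grid = "list",
                 bandwidth = "numeric", predictor = "TrainedPredictor"))

setMethod("show", "LandscapeProjection", function(object) {
  cat(sprintf(
    "LandscapeProjection (%s): %d points, axis kernels %d/%d, %dx%d grid\n",
    object@kind, nrow(object@points), object@kernels[1L],
    object@kernels[2L], length(object@grid$x), length(object@grid$y)))
})

.landscapeTarget <- function(kind) {
  switch(kind, host = "uninduced", mixed = "induced",
         orthogonal = "purified")
}

#' Build an activity landscape from penultimate feature maps
#'
#' Each sequence is placed at the per-sequence maxima of two kernels of the
#' last convolutional layer (the two with the largest variance of maxima
#' across the dataset, a deterministic and maximally informative choice);
#' the z-coordinate is the activity of the landscape's kind. A smooth
#' surface is fitted by Nadaraya-Watson kernel smoothing with bandwidth 5%
#' of each axis range.
#'
#' @param predictor CNN [TrainedPredictor-class] whose role matches `kind`
#'   (host landscapes come from uninduced-trained models, mixed from
#'   induced-trained, orthogonal from purified-trained).
#' @param records Activity `data.frame` carrying the kind's activity
#'   column.
#' @param kind `"host"`, `"mixed"` or `"orthogonal"`.
#' @param gridSize Grid resolution per axis (default 50).
#' @return A [LandscapeProjection-class].
#' @export
buildLandscape <- function(predictor, records,
                           kind = c("orthogonal", "host", "mixed"),
                           gridSize = 50L) {
  kind <- match.arg(kind)
  role <- switch(kind, host = "host", mixed = "mixed",
                 orthogonal = "orthogonal")
  if (predictor@role != role)
    stop(sprintf("a %s landscape needs a predictor with role '%s'",
                 kind, role))
  z <- records[[.landscapeTarget(kind)]]
  keep <- !is.na(z)
  records <- records[keep, , drop = FALSE]
  z <- z[keep]
  feats <- penultimateFeatures(predictor, records$sequence)
  maxima <- apply(feats, c(1L, 3L), max)          # n x 5 kernel maxima
  vars <- apply(maxima, 2L, stats::var)
  ord <- order(vars, decreasing = TRUE)
  usable <- ord[vars[ord] > 1e-12]
  if (length(usable) < 2L) {
    warning("fewer than two kernels with variable maxima; using first two")
    usable <- ord
  }
  kern <- usable[1:2]
  kx <- maxima[, kern[1L]]; ky <- maxima[, kern[2L]]
  bwx <- 0.05 * max(diff(range(kx)), 1e-9)
  bwy <- 0.05 * max(diff(range(ky)), 1e-9)
  gx <- seq(min(kx), max(kx), length.out = gridSize)
  gy <- seq(min(ky), max(ky), length.out = gridSize)
  wx <- exp(-0.5 * (outer(gx, kx, "-") / bwx)^2)   # gridSize x n
  wy <- exp(-0.5 * (outer(gy, ky, "-") / bwy)^2)
  # surface z(a,b) = sum_i wx[a,i] wy[b,i] z_i / sum_i wx[a,i] wy[b,i]
  num <- wx %*% (z * t(wy))
  den <- wx %*% t(wy)
  zg <- num / pmax(den, 1e-12)
  new("LandscapeProjection", kind = kind, kernels = as.integer(kern),
      points = data.frame(kx = kx, ky = ky, z = z),
      grid = list(x = gx, y = gy, z = zg), bandwidth = c(bwx, bwy),
      predictor = predictor)
}

#' Count peaks of a landscape grid
#'
#' A peak is a grid cell exceeding all eight neighbours by a prominence of
#' 2% of the surface's z-range, the operational definition of landscape
#' ruggedness.
#'
#' @param landscape A [LandscapeProjection-class].
#' @param prominence Required excess over neighbours as a fraction of the
#'   z-range (default 0.02).
#' @return Integer peak count.
#' @export
countLandscapePeaks <- function(landscape, prominence = 0.02) {
  z <- landscape@grid$z
  nr <- nrow(z); nc <- ncol(z)
  eps <- prominence * max(diff(range(z)), 1e-12)
  count <- 0L
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      nb <- z[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (z[i, j] >= max(nb[-5L]) + eps) count <- count + 1L
    }
  }
  count
}

#' Project an optimization route onto a landscape
#'
#' Projects the decoded sequences of a design trajectory (start, end, and
#' evenly spaced intermediates) onto the landscape's kernel axes.
#'
#' @param landscape A [LandscapeProjection-class].
#' @param traj A [DesignTrajectory-class].
#' @param nPoints Number of route points including start and end
#'   (default 10).
#' @return `data.frame` with `step`, `sequence`, `kx`, `ky`, `z`
#'   (predicted activity of the decoded sequence), ordered by step.
#' @export
projectTrajectory <- function(landscape, traj, nPoints = 10L) {
  steps <- traj@steps
  n <- nrow(steps)
  if (nPoints < 2L) stop("need at least start and end")
  pick <- unique(round(seq(1L, n, length.out = min(nPoints, n))))
  sel <- steps[pick, , drop = FALSE]
  feats <- penultimateFeatures(landscape@predictor, sel$sequence)
  maxima <- apply(feats, c(1L, 3L), max)
  data.frame(step = sel$step, sequence = sel$sequence,
             kx = maxima[, landscape@kernels[1L]],
             ky = maxima[, landscape@kernels[2L]],
             z = sel$predicted)
}

#' Plot a landscape (and optionally a route) to a file or device
#'
#' @param landscape A [LandscapeProjection-class].
#' @param route Optional route from [projectTrajectory()].
#' @param file Optional PNG path; when `NULL`, draws on the open device.
#' @return Invisibly `NULL`.
#' @export
plotLandscape <- function(landscape, route = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 750)
    on.exit(grDevices::dev.off())
  }
  g <- landscape@grid
  graphics::filled.contour(g$x, g$y, g$z,
    color.palette = grDevices::terrain.colors,
    plot.title = graphics::title(
      main = sprintf("%s landscape (kernels %d vs %d)", landscape@kind,
                     landscape@kernels[1L], landscape@kernels[2L]),
      xlab = sprintf("kernel %d max", landscape@kernels[1L]),
      ylab = sprintf("kernel %d max", landscape@kernels[2L])),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(landscape@points$kx, landscape@points$ky,
                       pch = 16, cex = 0.4, col = "grey30")
      if (!is.null(route)) {
        graphics::lines(route$kx, route$ky, lwd = 2, col = "red")
        graphics::points(route$kx[c(1, nrow(route))],
                         route$ky[c(1, nrow(route))],
                         pch = c(1, 17), cex = 1.5, col = "red")
      }
    })
  invisible(NULL)
}

#' Receptive field of a convolutional layer
#'
#' Closed-form width and input-offset mapping of the CNN's convolutional
#' layers (kernel 5, same padding, maxpool stride 2 after layers 2 and 4).
#' Feature-map position `p` (1-based) of layer `layerIndex` sees input
#' positions `mult * p + lo` to `mult * p + hi` (before clipping at the
#' sequence boundary).
#'
#' @param layerIndex Convolutional layer number (1-4).
#' @param L Input length (for clipping info).
#' @return List with `width`, `mult`, `lo`, `hi` and `window(p)` returning
#'   `c(from, to, clipped)` for a feature position.
#' @export
receptiveField <- function(layerIndex, L = 31L) {
  stopifnot(layerIndex %in% 1:4)
  m <- 1L; lo <- 0L; hi <- 0L
  ops <- list(c("conv"), c("conv"), c("pool", "conv"), c("conv"))
  for (l in seq_len(layerIndex)) {
    for (op in ops[[l]]) {
      if (op == "conv") {                 # k = 5, pad = 2
        lo <- lo - 2L * m
        hi <- hi + 2L * m
      } else {                            # maxpool k = 2, stride 2
        lo <- lo - m
        m <- 2L * m
      }
    }
  }
  force(L)
  list(width = hi - lo + 1L, mult = m, lo = lo, hi = hi,
       window = function(p) {
         from <- m * p + lo; to <- m * p + hi
         c(from = max(1L, from), to = min(L, to),
           clipped = as.integer(from < 1L || to > L))
       })
}

#' @rdname KernelMotif-class
#' @slot layer Convolutional layer index.
#' @slot kernel Kernel index within the layer.
#' @slot pwm Position weight matrix (width x 4, columns A,C,G,T; rows sum
#'   to 1).
#' @slot width Receptive-field width in bases.
#' @slot support Number of aligned (un-clipped) subsequences.
#' @slot empty `TRUE` when the kernel never activated on the batch.
#' @export
setClass("KernelMotif",
  representation(layer = "integer", kernel = "integer", pwm = "matrix",
                 width = "integer", support = "integer", empty = "logical"),
  validity = function(object) {
    if (!object@empty) {
      if (nrow(object@pwm) != object@width) return("pwm width mismatch")
      if (any(abs(rowSums(object@pwm) - 1) > 1e-9))
        return("pwm rows must sum to 1")
    }
    TRUE
  })

setMethod("show", "KernelMotif", function(object) {
  cat(sprintf("KernelMotif layer %d kernel %d (width %d, support %d)%s\n",
              object@layer, object@kernel, object@width, object@support,
              if (object@empty) " [empty]" else ""))
})

#' Extract maximal-activation motifs for every kernel of a layer
#'
#' For each kernel, takes each sequence's maximum-activation position in
#' the feature map, maps it back to the input through the layer's
#' receptive field, stacks the aligned subsequences (windows clipped by the
#' sequence edge are dropped) and normalises base counts into a PWM.
#'
#' @param predictor CNN [TrainedPredictor-class].
#' @param seqs Character vector of sequences (at least 50 for stable PWMs).
#' @param layer Convolutional layer index (default 1).
#' @return List of [KernelMotif-class], one per kernel.
#' @export
kernelMotifs <- function(predictor, seqs, layer = 1L) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  if (length(seqs) < 50L)
    warning("fewer than 50 sequences; PWMs may be unstable")
  L <- nchar(seqs[1L])
  rf <- receptiveField(layer, L)
  feats <- .convFeatures(predictor, seqs,
                         paste0("conv", layer))
  nk <- dim(feats)[3L]
  lapply(seq_len(nk), function(k) {
    fm <- feats[, , k, drop = FALSE]        # n x positions
    fm <- matrix(fm, dim(feats)[1L], dim(feats)[2L])
    activated <- apply(fm, 1L, max) > 0
    windows <- character(0)
    for (i in which(activated)) {
      p <- which.max(fm[i, ])
      w <- rf$window(p)
      if (w["clipped"] == 1L) next
      windows <- c(windows, substr(seqs[i], w["from"], w["to"]))
    }
    if (!length(windows)) {
      return(new("KernelMotif", layer = as.integer(layer),
                 kernel = as.integer(k),
                 pwm = matrix(numeric(0), 0L, 4L), width = rf$width,
                 support = 0L, empty = TRUE))
    }
    mat <- .seqCodeMatrix(windows)
    pwm <- t(apply(mat, 2L, function(col)
      tabulate(match(intToUtf8(col, multiple = TRUE), DNA_BASES4), 4L)))
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- DNA_BASES4
    new("KernelMotif", layer = as.integer(layer), kernel = as.integer(k),
        pwm = pwm, width = rf$width, support = length(windows),
        empty = FALSE)
  })
}

#' Information content of a PWM
#'
#' Per-position information (2 + sum p log2 p) of a motif's PWM.
#'
#' @param motif A [KernelMotif-class] or PWM matrix.
#' @return Numeric vector of bits per position.
#' @export
pwmInformation <- function(motif) {
  pwm <- if (is(motif, "KernelMotif")) motif@pwm else motif
  apply(pwm, 1L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Export motifs in MEME minimal format
#'
#' @param motifs List of [KernelMotif-class].
#' @param path Output path.
#' @return Invisibly the path.
#' @export
writeMemeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    if (m@empty) next
    writeLines(sprintf("MOTIF layer%d_kernel%d", m@layer, m@kernel), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m@pwm), m@support), con)
    for (i in seq_len(nrow(m@pwm)))
      writeLines(paste(sprintf("%.6f", m@pwm[i, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

# small t-SNE for display-only 2-D embeddings of motif vectors
.tsne2d <- function(X, perplexity = 10, iters = 400L, seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-D2[i, ] * beta); p[i] <- 0
      sp <- sum(p)
      if (sp < 1e-12) { beta <- beta / 2; next }
      p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      diff <- H - log(perplexity)
      if (abs(diff) < 1e-4) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, ] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
    vel <- Y * 0
    for (it in seq_len(iters)) {
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      mult <- 4 * (P * if (it < 100) 4 else 1 - Q) * num
      grad <- t(vapply(seq_len(n), function(i)
        colSums(sweep(-sweep(Y, 2L, Y[i, ], "-"), 1L, mult[i, ], "*")),
        numeric(2)))
      vel <- 0.8 * vel - 200 * grad
      Y <- Y + vel
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}

#' @rdname ClusterReport-class
#' @slot chosenK Number of clusters maximising the mean silhouette.
#' @slot silhouette `data.frame` of scanned `k` and mean silhouette score.
#' @slot membership Integer cluster assignment per motif.
#' @slot types Motif provenance labels (`"a"`/`"b"` for the two models).
#' @slot pure Integer vector of pure-cluster ids.
#' @slot embedding 2-D display embedding (t-SNE), one row per motif.
#' @export
setClass("ClusterReport",
  representation(chosenK = "integer", silhouette = "data.frame",
                 membership = "integer", types = "character",
                 pure = "integer", embedding = "matrix"))

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf(
    "ClusterReport: k = %d over %d motifs, %d pure cluster(s)\n",
    object@chosenK, length(object@membership), length(object@pure)))
})

#' Cluster kernel motifs from two models and find pure clusters
#'
#' Flattens the PWMs of both motif sets, k-means-clusters them in the
#' original flattened-PWM space with k chosen by the maximum mean
#' silhouette score over 5..min(30, n-1), and reports "pure" clusters:
#' at least three motifs of one model type, none of the other, and with
#' the cluster centroid at least the median pairwise distance of the full
#' set away from the nearest foreign point. A 2-D stochastic-neighbour
#' embedding is attached for display only.
#'
#' @param motifsA Motifs from the first model (e.g. purified-trained).
#' @param motifsB Motifs from the second model (e.g. mixed-trained).
#' @param seed Seed for k-means restarts and the embedding.
#' @param kRange Candidate cluster counts (truncated to `n - 1`).
#' @return A [ClusterReport-class].
#' @export
embedAndCluster <- function(motifsA, motifsB, seed = 1L, kRange = 5:30) {
  keep <- function(ms) Filter(function(m) !m@empty, ms)
  motifsA <- keep(motifsA); motifsB <- keep(motifsB)
  flat <- function(ms) t(vapply(ms, function(m) as.vector(m@pwm),
                                numeric(length(motifsA[[1L]]@pwm))))
  X <- rbind(flat(motifsA), flat(motifsB))
  types <- c(rep("a", length(motifsA)), rep("b", length(motifsB)))
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 motifs to cluster")
  kRange <- kRange[kRange <= n - 1L]
  if (!length(kRange)) {
    warning("too few motifs for the requested k range; truncating")
    kRange <- 2:(n - 1L)
  }
  D <- stats::dist(X)
  sil <- withSeed(childSeed(seed, 61L), {
    vapply(kRange, function(k) {
      km <- stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)
      mean(cluster::silhouette(km$cluster, D)[, 3L])
    }, numeric(1))
  })
  chosenK <- kRange[which.max(sil)]
  km <- withSeed(childSeed(seed, 62L),
                 stats::kmeans(X, centers = chosenK, nstart = 5L,
                               iter.max = 50L))
  medD <- stats::median(as.vector(D))
  Dm <- as.matrix(stats::dist(rbind(km$centers, X)))
  pure <- integer(0)
  for (cl in seq_len(chosenK)) {
    members <- which(km$cluster == cl)
    if (length(members) < 3L) next
    if (length(unique(types[members])) != 1L) next
    foreign <- which(types != types[members[1L]])
    if (!length(foreign)) next
    dCF <- min(Dm[cl, chosenK + foreign])
    if (dCF >= medD) pure <- c(pure, cl)
  }
  emb <- .tsne2d(X, seed = childSeed(seed, 63L))
  new("ClusterReport", chosenK = as.integer(chosenK),
      silhouette = data.frame(k = kRange, score = sil),
      membership = as.integer(km$cluster), types = types,
      pure = as.integer(pure), embedding = emb)
}
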