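# Sequence design against a trained orthogonal-activity predictor, with
# host-independence enforced both as a differentiable penalty during
# gradient ascent and as a hard post-hoc filter.

#' Default design configuration
#'
#' @param seed Global design seed.
#' @param eta Gradient step size (default 1).
#' @param maxIters Maximum gradient iterations (default 1000).
#' @param poolSize Mutant-pool size for semi-rational design
#'   (default 10000).
#' @param maxEdit Maximum substitutions from the wild type in the pool
#'   (default 8).
#' @param minPairwise Minimum pairwise Hamming distance among emitted
#'   semi-rational designs (default 8).
#' @param hostLambda Weight of the host-activity penalty in the de novo
#'   objective (default 1).
#' @param tolerance Relative deviation from the target activity at which a
#'   design counts as converged (default 0.1).
#' @param tau1 Host-activity threshold: designs predicted at or above it
#'   are host-contaminated and rejected (default 10 activity units).
#' @param objective `"deviation"` targets a level directly after an
#'   initial climb; `"maximize"` ascends throughout and harvests target
#'   levels from the trajectory.
#' @param climbIters Length of the initial activity-maximising phase of a
#'   de novo run (default 250 steps).
#' @param nStarts Climb attempts per de novo design: a climb ending below
#'   0.7 of the top target under the smoothed prediction restarts from a
#'   fresh random sequence (default 4).
#' @param smoothEvery Interval (in steps) between smoothed re-scorings of
#'   near-target designs (default 5).
#' @param descentPositions Number of positions updated per step during the
#'   target-matching descent (default 2).
#' @param descentLeash Maximum Hamming distance from the climb-end
#'   sequence at which descent candidates may be harvested (default 10);
#'   keeps the attenuated design anchored to the functional core it
#'   climbed to instead of wandering into poorly modelled space.
#' @return Named list of configuration values.
#' @export
designConfig <- function(seed = 1L, eta = 1, maxIters = 1000L,
                         poolSize = 10000L, maxEdit = 8L, minPairwise = 8L,
                         hostLambda = 1, tolerance = 0.1, tau1 = 10,
                         objective = c("deviation", "maximize"),
                         climbIters = 250L, nStarts = 4L,
                         smoothEvery = 5L, descentPositions = 2L,
                         descentLeash = 10L) {
  stopifnot(eta > 0, maxIters >= 1L, minPairwise >= 0L, nStarts >= 1L)
  objective <- match.arg(objective)
  list(seed = seed, eta = eta, maxIters = as.integer(maxIters),
       poolSize = as.integer(poolSize), maxEdit = as.integer(maxEdit),
       minPairwise = as.integer(minPairwise), hostLambda = hostLambda,
       tolerance = tolerance, tau1 = tau1, objective = objective,
       climbIters = as.integer(climbIters), nStarts = as.integer(nStarts),
       smoothEvery = as.integer(smoothEvery),
       descentPositions = as.integer(descentPositions),
       descentLeash = as.integer(descentLeash))
}

#' Default target level menus
#'
#' `semiRationalLevels()` returns the eight range-design levels (fractions
#' of the wild-type activity) with their default allocation summing to 58
#' designs (as even as possible, remainder on the middle levels);
#' `deNovoLevels()` returns the eleven de novo levels with an allocation
#' summing to 41.
#'
#' @return `data.frame` with columns `level` and `count`.
#' @export
semiRationalLevels <- function() {
  lv <- c(1, 2/3, 1/2, 1/3, 1/4, 1/8, 1/16, 1/32)
  count <- rep(58L %/% 8L, 8L)
  extra <- 58L %% 8L                      # spread remainder on middle levels
  mid <- order(abs(seq_along(lv) - (length(lv) + 1) / 2))[seq_len(extra)]
  count[mid] <- count[mid] + 1L
  data.frame(level = lv, count = count)
}

#' @rdname semiRationalLevels
#' @export
deNovoLevels <- function() {
  lv <- c(5/4, 3/4, 1/2, 1/3, 1/4, 1/6, 1/8, 1/12, 1/16, 1/24, 1/32)
  count <- rep(41L %/% 11L, 11L)
  extra <- 41L %% 11L
  mid <- order(abs(seq_along(lv) - (length(lv) + 1) / 2))[seq_len(extra)]
  count[mid] <- count[mid] + 1L
  data.frame(level = lv, count = count)
}

#' @rdname DesignSet-class
#' @slot designs `data.frame` with one row per emitted design: `id`,
#'   `sequence`, `targetLevel`, `predicted`, `predictedHost`,
#'   `hammingToWT`, `provenance`, `converged`.
#' @slot wt The wild-type reference sequence.
#' @slot config The design configuration used.
#' @slot constraints List of constraint settings and any shortfalls.
#' @export
setClass("DesignSet",
  representation(designs = "data.frame", wt = "character", config = "list",
                 constraints = "list"),
  validity = function(object) {
    if (anyDuplicated(object@designs$sequence))
      return("design sequences must be unique")
    TRUE
  })

setMethod("show", "DesignSet", function(object) {
  d <- object@designs
  cat(sprintf("DesignSet: %d designs (%s), wt %s\n", nrow(d),
              paste(unique(d$provenance), collapse = "/"), object@wt))
  if (nrow(d) >= 2L)
    cat(sprintf("  min pairwise Hamming %d, Hamming to wt %d-%d\n",
                minPairwiseHamming(d$sequence), min(d$hammingToWT),
                max(d$hammingToWT)))
})

#' Designs of a design set
#' @param set A [DesignSet-class].
#' @return The designs `data.frame`.
#' @export
designRecords <- function(set) set@designs

#' @rdname DesignTrajectory-class
#' @slot steps `data.frame` with `step`, `sequence` (decoded), `predicted`,
#'   `predictedHost`; step 0 is the random start, the last row the final
#'   state.
#' @slot best Row index of the returned (best-so-far) design.
#' @slot target Target activity (linear scale).
#' @slot encodings Optional list of relaxed-encoding snapshots.
#' @export
setClass("DesignTrajectory",
  representation(steps = "data.frame", best = "integer", target = "numeric",
                 encodings = "list"))

setMethod("show", "DesignTrajectory", function(object) {
  n <- nrow(object@steps)
  cat(sprintf(
    "DesignTrajectory: %d steps, target %.3g; start %.3g -> best %.3g\n",
    n - 1L, object@target, object@steps$predicted[1L],
    object@steps$predicted[object@best]))
})

# greedy pick of `count` candidates closest to `target` among `pred`,
# honouring a minimum Hamming distance to everything already selected;
# ties on closeness go to the candidate farthest from the selection
.greedyPick <- function(seqs, pred, target, count, selectedSeqs, minPairwise) {
  picked <- integer(0)
  minDist <- if (length(selectedSeqs))
    apply(vapply(selectedSeqs, function(s) hammingToAll(s, seqs),
                 numeric(length(seqs))), 1L, min)
  else rep(Inf, length(seqs))
  diffs <- abs(pred - target)
  avail <- rep(TRUE, length(seqs))
  while (length(picked) < count) {
    ok <- avail & minDist >= minPairwise
    if (!any(ok)) break
    d <- diffs; d[!ok] <- Inf
    m <- min(d)
    cand <- which(d <= m + 1e-9)
    pick <- cand[which.max(minDist[cand])]
    picked <- c(picked, pick)
    avail[pick] <- FALSE
    minDist <- pmin(minDist, hammingToAll(seqs[pick], seqs))
  }
  picked
}

#' Semi-rational design of defined-strength promoter sets
#'
#' Generates a bounded-mutation pool around the wild type, removes
#' candidates the host predictor calls active, and for each target level
#' greedily selects the candidates whose predicted activity is nearest
#' `level * predicted wild-type activity`, subject to a minimum pairwise
#' Hamming distance among all selected designs. Levels are processed from
#' the highest down, since high-activity candidates are the most
#' distance-constrained.
#'
#' @param predictor Orthogonal-activity [TrainedPredictor-class].
#' @param hostPredictor Host-activity [TrainedPredictor-class].
#' @param wt Wild-type sequence.
#' @param targets `data.frame(level, count)`; default [semiRationalLevels()]
#'   (58 designs over 8 levels).
#' @param cfg Configuration from [designConfig()].
#' @return A [DesignSet-class].
#' @export
semiRational <- function(predictor, hostPredictor, wt,
                         targets = semiRationalLevels(),
                         cfg = designConfig()) {
  wt <- checkDNA(wt)
  pool <- generateMutantLibrary(wt, cfg$poolSize, cfg$maxEdit,
                                seed = childSeed(cfg$seed, 31L))
  hostPred <- predictActivity(hostPredictor, pool)
  keep <- hostPred < cfg$tau1
  poolSeqs <- pool[keep]
  poolHost <- hostPred[keep]
  poolPred <- predictActivity(predictor, poolSeqs)
  Twt <- predictActivity(predictor, wt)
  targets <- targets[order(-targets$level), , drop = FALSE]
  selected <- data.frame()
  shortfall <- list()
  for (i in seq_len(nrow(targets))) {
    lvl <- targets$level[i]
    idx <- .greedyPick(poolSeqs, poolPred, lvl * Twt, targets$count[i],
                       selected$sequence, cfg$minPairwise)
    if (length(idx) < targets$count[i])
      shortfall[[sprintf("level_%g", lvl)]] <-
        targets$count[i] - length(idx)
    if (length(idx))
      selected <- rbind(selected, data.frame(
        sequence = poolSeqs[idx], targetLevel = lvl,
        predicted = poolPred[idx], predictedHost = poolHost[idx],
        stringsAsFactors = FALSE))
    # drop picked candidates from the pool
    if (length(idx)) {
      poolSeqs <- poolSeqs[-idx]; poolPred <- poolPred[-idx]
      poolHost <- poolHost[-idx]
    }
  }
  selected <- selected[order(-selected$targetLevel, selected$sequence), ,
                       drop = FALSE]
  d <- data.frame(id = sprintf("sr%02d", seq_len(nrow(selected))),
                  selected,
                  hammingToWT = hammingToAll(wt, selected$sequence),
                  provenance = "semi_rational",
                  converged = abs(selected$predicted -
                                    selected$targetLevel * Twt) <=
                    cfg$tolerance * selected$targetLevel * Twt,
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  new("DesignSet", designs = d, wt = wt, config = cfg,
      constraints = list(minPairwise = cfg$minPairwise, tau1 = cfg$tau1,
                         maxEdit = cfg$maxEdit, predictedWT = Twt,
                         shortfall = shortfall))
}

#' Diverse designs at one fixed activity level
#'
#' Restricts the mutant pool to candidates whose predicted activity lies in
#' a band of at most 1.51-fold spread around `level * predicted wild-type
#' activity`, then maximises sequence diversity by greedy farthest-point
#' selection on Hamming distance.
#'
#' @param predictor Orthogonal-activity [TrainedPredictor-class].
#' @param wt Wild-type sequence.
#' @param level Target fraction of wild-type activity (default 1/16).
#' @param n Number of designs (default 12).
#' @param cfg Configuration from [designConfig()].
#' @param hostPredictor Optional host predictor; when given, host-active
#'   candidates are removed first.
#' @param maxSpread Maximum allowed max/min predicted ratio (default 1.51).
#' @return A [DesignSet-class].
#' @export
fixedLevelDiverse <- function(predictor, wt, level = 1/16, n = 12L,
                              cfg = designConfig(), hostPredictor = NULL,
                              maxSpread = 1.51) {
  wt <- checkDNA(wt)
  pool <- generateMutantLibrary(wt, cfg$poolSize, cfg$maxEdit,
                                seed = childSeed(cfg$seed, 32L))
  poolHost <- rep(0, length(pool))
  if (!is.null(hostPredictor)) {
    poolHost <- predictActivity(hostPredictor, pool)
    keep <- poolHost < cfg$tau1
    pool <- pool[keep]; poolHost <- poolHost[keep]
  }
  pred <- predictActivity(predictor, pool)
  Twt <- predictActivity(predictor, wt)
  target <- level * Twt
  s <- sqrt(maxSpread)
  inBand <- pred > 0 & pred >= target / s & pred <= target * s
  if (sum(inBand) < n) {
    rel <- sort(pmax(pred / target, target / pmax(pred, 1e-12)))
    stop(sprintf(
      "only %d candidates within %.2f-fold of the target; nearest achievable spread for %d designs is %.2f-fold",
      sum(inBand), maxSpread, n, rel[n]^2))
  }
  cand <- which(inBand)
  picked <- .farthestPointPick(pool[cand], pred[cand], target, n)
  picked <- cand[picked]
  d <- data.frame(id = sprintf("fx%02d", seq_along(picked)),
                  sequence = pool[picked], targetLevel = level,
                  predicted = pred[picked], predictedHost = poolHost[picked],
                  hammingToWT = hammingToAll(wt, pool[picked]),
                  provenance = "fixed_level",
                  converged = TRUE, stringsAsFactors = FALSE)
  new("DesignSet", designs = d, wt = wt, config = cfg,
      constraints = list(level = level, maxSpread = maxSpread,
                         predictedWT = Twt,
                         spread = max(d$predicted) / min(d$predicted)))
}

# multi-start greedy farthest-point (max-min Hamming) selection of n
# candidates: every candidate seeds one greedy run and the most diverse
# selection wins; distance ties go to the candidate closest to the target
.farthestPointPick <- function(seqs, pred, target, n) {
  m <- length(seqs)
  if (n == 1L) return(which.min(abs(pred - target)))
  D <- NULL
  if (m <= 400L) {                      # precompute for multi-start
    code <- .seqCodeMatrix(seqs)
    D <- matrix(0L, m, m)
    for (i in seq_len(m - 1L)) {
      d <- rowSums(code[(i + 1L):m, , drop = FALSE] !=
                     matrix(code[i, ], m - i, ncol(code), byrow = TRUE))
      D[i, (i + 1L):m] <- d; D[(i + 1L):m, i] <- d
    }
  }
  distTo <- function(i) if (is.null(D)) hammingToAll(seqs[i], seqs) else D[i, ]
  greedyFrom <- function(first) {
    picked <- first
    md <- distTo(first)
    while (length(picked) < n) {
      avail <- setdiff(seq_len(m), picked)
      best <- max(md[avail])
      tied <- avail[md[avail] >= best - 1e-9]
      nxt <- tied[which.min(abs(pred[tied] - target))]
      picked <- c(picked, nxt)
      md <- pmin(md, distTo(nxt))
    }
    picked
  }
  seeds <- if (is.null(D)) which.min(abs(pred - target)) else seq_len(m)
  bestPick <- NULL; bestScore <- -Inf
  for (s in seeds) {
    pk <- greedyFrom(s)
    sc <- if (is.null(D)) minPairwiseHamming(seqs[pk]) else
      min(D[pk, pk][upper.tri(diag(length(pk)))])
    if (sc > bestScore ||
        (sc == bestScore &&
           sum(abs(pred[pk] - target)) < sum(abs(pred[bestPick] - target)))) {
      bestScore <- sc; bestPick <- pk
    }
  }
  bestPick
}

# z-scale prediction for relaxed encodings (forward only)
.relaxedZ <- function(predictor, X) {
  if (predictor@model$arch == "cnn")
    .cnnForwardCpp(X, predictor@model$layers)$pred
  else nnForward(predictor@model, X)$pred
}

# z-scale prediction and gradient of sum(w_i * z_i) for relaxed encodings
.relaxedZGrad <- function(predictor, X, w) {
  m <- predictor@model
  if (m$arch == "cnn") {
    g <- .cnnGradCpp(X, m$layers, w, TRUE)
    list(z = g$pred, grad = g$dX)
  } else {
    fw <- nnForward(m, X)
    bw <- nnBackward(m, fw$cache, w)
    list(z = fw$pred, grad = bw$dX)
  }
}

.zFromLinear <- function(predictor, a) {
  (.transformY(a, predictor@responseScale) - predictor@yCenter) /
    predictor@yScale
}

.linearFromZ <- function(predictor, z) {
  .invTransformY(z * predictor@yScale + predictor@yCenter,
                 predictor@responseScale)
}

# Core batched gradient-design loop; targets is a vector of linear-scale
# target activities, one per design.
#
# Scheme, in four parts (each documented in the methods vignette):
#  - Straight-through gradients: the relaxed encoding x accumulates
#    gradient steps, but each gradient is evaluated at the decoded hard
#    encoding. A freely drifting relaxed point leaves the data manifold
#    within a few steps and meets the objective "out of distribution"
#    while its argmax decoding stays poor; gradients taken at the decoded
#    one-hot always describe real sequences.
#  - Climb-then-match with restarts: every run first ascends predicted
#    activity for cfg$climbIters steps, assembling a functional core in
#    the region where the model is calibrated, and only then descends to
#    its target level. A climb whose end point scores poorly under the
#    smoothed prediction (below half the top target) is a hallucinated
#    ridge; such designs restart from a fresh random sequence, up to
#    cfg$nStarts attempts. Under cfg$objective = "maximize" the ascent
#    runs throughout and target levels are harvested from the trajectory.
#  - Masked descent: during the matching phase only the
#    cfg$descentPositions positions with the largest gradient norm are
#    updated per step (the search mutates one to three bases at a time),
#    and the relaxed encoding is reset to the decoded one-hot at the
#    phase switch, so the design attenuates its core instead of drifting
#    through poorly modelled sequence space.
#  - Smoothed harvesting: while a design sits near its target, its
#    decoded sequence is periodically re-scored by the median model
#    prediction over the sequence and all its single mutants; sharp
#    out-of-distribution optima score poorly under this neighbourhood
#    median while genuine activity survives it. The harvested design and
#    its reported prediction come from the best smoothed score.
.gradientDesign <- function(predictor, hostPredictor, targets, cfg,
                            recordEvery = TRUE, wt = NULL) {
  B <- length(targets)
  L <- predictor@model$L
  starts <- generateRandomLibrary(B, L, seed = childSeed(cfg$seed, 41L))
  X <- encodeOneHotBatch(starts)
  zTarget <- .zFromLinear(predictor, targets)
  zMax <- .zFromLinear(predictor, max(targets))
  zTau <- .zFromLinear(hostPredictor, cfg$tau1)
  maximize <- cfg$objective == "maximize"
  climb <- if (maximize) cfg$maxIters else min(cfg$climbIters, cfg$maxIters)
  smoothEvery <- max(1L, cfg$smoothEvery)
  active <- rep(TRUE, B)
  climbEnd <- rep(climb, B)
  deadline <- rep(Inf, B)     # per-attempt iteration budget (descent end)
  attempts <- rep(1L, B)
  best <- list(seq = starts, pred = rep(NA_real_, B),
               host = rep(NA_real_, B), score = rep(Inf, B),
               step = rep(0L, B), smoothed = rep(FALSE, B))
  fallback <- best
  climbSeq <- starts          # overwritten at each design's descent entry
  lastSmoothed <- rep("", B)
  traj <- vector("list", B)
  dec <- starts
  step <- 0L
  repeat {
    idx <- which(active)
    H <- encodeOneHotBatch(dec[idx])
    z <- .relaxedZ(predictor, H)
    zh <- .relaxedZ(hostPredictor, H)
    predDec <- .linearFromZ(predictor, z)
    hostDec <- .linearFromZ(hostPredictor, zh)
    # end-of-climb gate: restart hallucinated climbs, reset the rest
    gate <- which(!maximize & step == climbEnd[idx])
    if (length(gate)) {
      bb <- idx[gate]
      sm <- .smoothedPredict(predictor, dec[bb])
      radius <- cfg$maxEdit + cfg$descentLeash
      for (j in seq_along(bb)) {
        b <- bb[j]
        outOfSupport <- !is.null(wt) &&
          hammingDist(dec[b], wt) > radius
        if ((sm[j] < 0.7 * max(targets) || outOfSupport) &&
            attempts[b] < cfg$nStarts) {
          # a restart is a fresh optimisation run with its own budget
          attempts[b] <- attempts[b] + 1L
          fresh <- generateRandomLibrary(
            1L, L, seed = childSeed(cfg$seed, 410L + 17L * b + attempts[b]))
          dec[b] <- fresh
          X[b, , ] <- encodeOneHot(fresh)
          climbEnd[b] <- step + climb
        } else {
          X[b, , ] <- encodeOneHot(dec[b])   # descend from a clean state
          climbSeq[b] <- dec[b]
          deadline[b] <- step + (cfg$maxIters - climb)
        }
      }
    }
    harvest <- maximize | step > climbEnd[idx] | climbEnd[idx] == 0L
    for (i in seq_along(idx)) {
      b <- idx[i]
      score <- abs(predDec[i] - targets[b]) +
        if (hostDec[i] >= cfg$tau1) Inf else 0
      leashed <- maximize || climbEnd[b] == 0L ||
        hammingDist(dec[b], climbSeq[b]) <= cfg$descentLeash
      if (harvest[i] && leashed && !best$smoothed[b] &&
          score < best$score[b]) {
        best$seq[b] <- dec[b]; best$pred[b] <- predDec[i]
        best$host[b] <- hostDec[i]; best$score[b] <- score
        best$step[b] <- step
      }
      if (score < fallback$score[b]) {
        fallback$seq[b] <- dec[b]; fallback$pred[b] <- predDec[i]
        fallback$host[b] <- hostDec[i]; fallback$score[b] <- score
        fallback$step[b] <- step
      }
      if (recordEvery || is.null(traj[[b]]) ||
          dec[b] != traj[[b]]$sequence[nrow(traj[[b]])]) {
        traj[[b]] <- rbind(traj[[b]], data.frame(
          step = step, sequence = dec[b], predicted = predDec[i],
          predictedHost = hostDec[i], stringsAsFactors = FALSE))
      }
    }
    # periodic smoothed re-scoring of designs sitting near their targets
    if (step %% smoothEvery == 0L) {
      drift <- vapply(seq_along(idx), function(i)
        if (maximize || climbEnd[idx[i]] == 0L) 0L else
          hammingDist(dec[idx[i]], climbSeq[idx[i]]), integer(1))
      inBand <- which(harvest & hostDec < cfg$tau1 &
                        drift <= cfg$descentLeash &
                        abs(predDec - targets[idx]) <=
                          max(3 * cfg$tolerance, 0.3) * targets[idx] &
                        dec[idx] != lastSmoothed[idx])
      if (length(inBand)) {
        bb <- idx[inBand]
        lastSmoothed[bb] <- dec[bb]
        smPred <- .smoothedPredict(predictor, dec[bb])
        for (j in seq_along(bb)) {
          b <- bb[j]
          sc <- abs(smPred[j] - targets[b])
          if (!best$smoothed[b] || sc < best$score[b]) {
            best$seq[b] <- dec[b]; best$pred[b] <- smPred[j]
            best$host[b] <- hostDec[inBand[j]]; best$score[b] <- sc
            best$step[b] <- step; best$smoothed[b] <- TRUE
          }
          if (sc <= cfg$tolerance * targets[b]) active[b] <- FALSE
        }
      }
    }
    active[idx[step >= deadline[idx]]] <- FALSE
    if (!any(active) || step >= cfg$nStarts * climb + cfg$maxIters) break
    step <- step + 1L
    idx <- which(active)
    Hi <- if (length(idx) == dim(H)[1L]) H else encodeOneHotBatch(dec[idx])
    zi <- .relaxedZ(predictor, Hi)
    inClimb <- maximize | step <= climbEnd[idx]
    wOrth <- ifelse(inClimb, -2 * pmin(zi - zMax, 0),
                    -2 * (zi - zTarget[idx]))
    g <- .relaxedZGrad(predictor, Hi, wOrth)$grad
    zhi <- .relaxedZ(hostPredictor, Hi)
    hinge <- as.numeric(zhi > zTau)
    if (any(hinge > 0))
      g <- g + .relaxedZGrad(hostPredictor, Hi,
                             -cfg$hostLambda * hinge)$grad
    if (any(!is.finite(g))) break
    Xa0 <- X[idx, , , drop = FALSE]
    k <- cfg$descentPositions
    # masked descent (few positions per step) applies to the matching
    # phase after a real climb; runs without a climb phase are plain
    # deviation searches
    for (i in which(!inClimb & climbEnd[idx] > 0L)) {
      gi <- matrix(g[i, , ], L, 4L)
      keepPos <- order(rowSums(gi^2), decreasing = TRUE)[seq_len(k)]
      gi[-keepPos, ] <- 0
      g[i, , ] <- gi
    }
    Xa <- Xa0 + cfg$eta * g
    X[idx, , ] <- Xa
    dec[idx] <- vapply(seq_along(idx), function(i)
      decodeArgmax(matrix(Xa[i, , ], L, 4L)), character(1))
  }
  # designs that never reached a harvest window fall back to their best
  # point-score step from any phase
  for (b in which(is.na(best$pred))) {
    best$seq[b] <- fallback$seq[b]; best$pred[b] <- fallback$pred[b]
    best$host[b] <- fallback$host[b]; best$score[b] <- fallback$score[b]
    best$step[b] <- fallback$step[b]
  }
  list(best = best, traj = traj, starts = starts, stepsRun = step,
       attempts = attempts)
}

# all single-substitution mutants of a sequence
.allSingleMutants <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  out <- character(3L * L)
  k <- 0L
  for (p in seq_len(L)) {
    for (b in setdiff(DNA_BASES4, ch[p])) {
      c2 <- ch; c2[p] <- b
      k <- k + 1L
      out[k] <- paste(c2, collapse = "")
    }
  }
  out
}

# neighbourhood-median (smoothed) model prediction for each sequence:
# the median prediction over the sequence and all its single mutants
.smoothedPredict <- function(predictor, seqs) {
  batch <- unlist(lapply(seqs, function(s) c(s, .allSingleMutants(s))))
  preds <- predictActivity(predictor, batch)
  per <- 3L * nchar(seqs[1L]) + 1L
  vapply(seq_along(seqs), function(j)
    stats::median(preds[(j - 1L) * per + seq_len(per)]), numeric(1))
}



#' De novo design of one sequence by gradient ascent
#'
#' Starts from a uniformly random sequence, relaxes its one-hot encoding to
#' real values, and iterates `x <- x + eta * grad J(x)` where `J` is the
#' negative squared deviation of the predicted activity from the target
#' (on the model's standardised log scale) minus a hinge penalty on
#' predicted host activity above the host threshold. After every step the
#' encoding is decoded by per-position argmax; the returned design is the
#' best decoded sequence seen along the trajectory (fixed-step gradient
#' ascent can overshoot, so the final iterate need not be the best).
#'
#' @param predictor Orthogonal-activity [TrainedPredictor-class].
#' @param hostPredictor Host-activity [TrainedPredictor-class].
#' @param targetLevel Target fraction of the predicted wild-type activity
#'   (or of `Tref` when given).
#' @param cfg Configuration from [designConfig()].
#' @param Tref Reference activity defining level 1; defaults to the
#'   predicted activity of `wt`.
#' @param wt Wild-type sequence used for `Tref` and distance reporting.
#' @return List with `sequence` and `trajectory`
#'   (a [DesignTrajectory-class]).
#' @export
deNovoDesign <- function(predictor, hostPredictor, targetLevel, cfg =
                           designConfig(), wt = NULL, Tref = NULL) {
  if (is.null(Tref)) {
    if (is.null(wt)) stop("give either wt or Tref")
    Tref <- predictActivity(predictor, wt)
  }
  res <- .gradientDesign(predictor, hostPredictor, targetLevel * Tref, cfg,
                         recordEvery = TRUE, wt = wt)
  steps <- res$traj[[1L]]
  bestRow <- which(steps$sequence == res$best$seq[1L])[1L]
  if (is.na(bestRow)) bestRow <- nrow(steps)
  traj <- new("DesignTrajectory", steps = steps,
              best = as.integer(bestRow),
              target = targetLevel * Tref, encodings = list())
  list(sequence = res$best$seq[1L], trajectory = traj)
}

#' Batch de novo design over a level menu
#'
#' Runs one gradient design per requested sequence (batched internally),
#' each from an independent random start with a seed derived from the
#' configuration seed.
#'
#' @param predictor Orthogonal-activity [TrainedPredictor-class].
#' @param hostPredictor Host-activity [TrainedPredictor-class].
#' @param targets `data.frame(level, count)`; default [deNovoLevels()]
#'   (41 designs over 11 levels).
#' @param cfg Configuration from [designConfig()].
#' @param wt Wild-type sequence (reference activity and distances).
#' @return A [DesignSet-class]; per-design compact trajectories are stored
#'   in the constraints list.
#' @export
batchDeNovo <- function(predictor, hostPredictor, targets = deNovoLevels(),
                        cfg = designConfig(), wt) {
  wt <- checkDNA(wt)
  Twt <- predictActivity(predictor, wt)
  levels <- rep(targets$level, targets$count)
  res <- .gradientDesign(predictor, hostPredictor, levels * Twt, cfg,
                         recordEvery = FALSE, wt = wt)
  seqs <- res$best$seq
  # regenerate any duplicated design from a fresh start
  tries <- 0L
  while (anyDuplicated(seqs) && tries < 5L) {
    tries <- tries + 1L
    dup <- which(duplicated(seqs))
    cfg2 <- cfg
    cfg2$seed <- childSeed(cfg$seed, 900L + tries)
    r2 <- .gradientDesign(predictor, hostPredictor, levels[dup] * Twt,
                          cfg2, recordEvery = FALSE, wt = wt)
    seqs[dup] <- r2$best$seq
    res$best$pred[dup] <- r2$best$pred
    res$best$host[dup] <- r2$best$host
  }
  d <- data.frame(id = sprintf("dn%02d", seq_along(seqs)),
                  sequence = seqs, targetLevel = levels,
                  predicted = res$best$pred,
                  predictedHost = res$best$host,
                  hammingToWT = hammingToAll(wt, seqs),
                  provenance = "de_novo",
                  converged = abs(res$best$pred - levels * Twt) <=
                    cfg$tolerance * levels * Twt,
                  stringsAsFactors = FALSE)
  new("DesignSet", designs = d, wt = wt, config = cfg,
      constraints = list(tau1 = cfg$tau1, predictedWT = Twt,
                         trajectories = res$traj,
                         stepsRun = res$stepsRun))
}

#' Validate a design set against the generating oracles
#'
#' Simulates induced and uninduced replicate measurements for every design,
#' purifies them by subtraction, and reports the agreement between the
#' designer's predicted activities and the oracle-evaluated purified
#' activities.
#'
#' @param set A [DesignSet-class].
#' @param orth,host The ground-truth oracles.
#' @param mm A [MeasurementModel-class].
#' @param seed Measurement seed.
#' @return List with `pearsonR`, `R2`, `mse`, `n`, and the per-design
#'   `evaluated` activities.
#' @export
validateDesigns <- function(set, orth, host, mm = MeasurementModel(),
                            seed = 1L) {
  d <- set@designs
  mi <- measureActivity(d$sequence, TRUE, orth, host, mm,
                        seed = childSeed(seed, 51L))
  mu <- measureActivity(d$sequence, FALSE, orth, host, mm,
                        seed = childSeed(seed, 52L))
  purified <- pmax(0, rowMeans(mi) - rowMeans(mu))
  r <- stats::cor(d$predicted, purified)
  list(pearsonR = r, R2 = r^2,
       mse = mean((d$predicted - purified)^2), n = nrow(d),
       evaluated = purified)
}

#' Write a design set to FASTA plus a TSV manifest
#'
#' @param set A [DesignSet-class].
#' @param fastaPath,manifestPath Output paths (either may be `NULL`).
#' @return Invisibly, the manifest `data.frame`.
#' @export
writeDesignSet <- function(set, fastaPath = NULL, manifestPath = NULL) {
  d <- set@designs
  if (!is.null(fastaPath))
    writeFastaSeqs(stats::setNames(d$sequence, d$id), fastaPath)
  if (!is.null(manifestPath))
    utils::write.table(d, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(d)
}
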