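# Synthetic ground truth for the insulated cis-trans system.
#
# The simulator realises the working hypothesis behind host-effect
# purification: observed induced expression is the sum, on the linear
# fluorescence scale, of a smooth "orthogonal" component (the phage
# polymerase reading its cognate promoter) and a rugged "host" component
# (the host polymerase firing off cryptic promoters), so that subtracting
# the uninduced readout recovers the orthogonal part exactly in the
# noise-free limit.

# evaluate expr with a deterministic, locally scoped RNG
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a stream-specific child seed from a global seed (stays < 2^31)
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629
}

#' @rdname OrthogonalOracle-class
#' @slot wt Wild-type sequence (character scalar, length L).
#' @slot penalty L x 4 non-negative matrix of per-position mismatch
#'   penalties, zero at the wild-type base of each position.
#' @slot Tmax Activity of the wild type (arbitrary fluorescence units).
#' @slot beta Smoothness coefficient multiplying the summed penalty.
#' @slot pairs Optional 3-column matrix (i, j, penalty) of pairwise
#'   epistatic penalties applied when both positions are mutated; zero rows
#'   give a purely additive landscape.
#' @export
setClass("OrthogonalOracle",
  representation(wt = "character", penalty = "matrix", Tmax = "numeric",
                 beta = "numeric", pairs = "matrix"),
  validity = function(object) {
    L <- nchar(object@wt)
    wtIdx <- match(strsplit(object@wt, "")[[1L]], DNA_BASES4)
    if (!all(dim(object@penalty) == c(L, 4L)))
      return("penalty must be L x 4")
    if (any(object@penalty < 0)) return("penalties must be non-negative")
    if (any(abs(object@penalty[cbind(seq_len(L), wtIdx)]) > 1e-12))
      return("penalty at the wild-type base must be 0")
    if (object@Tmax <= 0 || object@beta <= 0)
      return("Tmax and beta must be positive")
    TRUE
  })

#' @rdname HostOracle-class
#' @slot motifs List of k x 4 score matrices (host polymerase preferences).
#' @slot threshold Window score that must be exceeded before a window
#'   contributes.
#' @slot gain Linear gain applied to summed above-threshold window scores.
#' @slot hotSeqs Character vector of exact subsequences ("cryptic host
#'   promoters") that add a fixed activity boost wherever they occur.
#' @slot hotBoost Numeric vector of boosts, parallel to `hotSeqs`.
#' @export
setClass("HostOracle",
  representation(motifs = "list", threshold = "numeric", gain = "numeric",
                 hotSeqs = "character", hotBoost = "numeric"),
  validity = function(object) {
    if (length(object@hotSeqs) != length(object@hotBoost))
      return("hotSeqs and hotBoost must be parallel")
    if (object@gain < 0) return("gain must be non-negative")
    TRUE
  })

#' @rdname MeasurementModel-class
#' @slot noiseSigma Standard deviation of multiplicative lognormal
#'   measurement noise (flow-cytometry fluorescence is close to lognormal).
#' @slot floor Detection floor; measurements below it are reported at the
#'   floor.
#' @slot replicates Number of independent replicate measurements (default 3).
#' @export
setClass("MeasurementModel",
  representation(noiseSigma = "numeric", floor = "numeric",
                 replicates = "integer"),
  validity = function(object) {
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@floor < 0) return("floor must be >= 0")
    if (object@replicates < 1L) return("need at least 1 replicate")
    TRUE
  })

#' Measurement model constructor
#'
#' @param noiseSigma Lognormal noise sd on the log scale.
#' @param floor Detection floor in activity units.
#' @param replicates Number of replicates.
#' @return A [MeasurementModel-class] object.
#' @export
MeasurementModel <- function(noiseSigma = 0.1, floor = 0.1, replicates = 3L) {
  new("MeasurementModel", noiseSigma = noiseSigma, floor = floor,
      replicates = as.integer(replicates))
}

setMethod("show", "OrthogonalOracle", function(object) {
  cat(sprintf("OrthogonalOracle: L = %d, Tmax = %.3g, beta = %.3g, %s\n",
              nchar(object@wt), object@Tmax, object@beta,
              if (nrow(object@pairs)) sprintf("%d epistatic pairs",
                                              nrow(object@pairs))
              else "additive"))
  cat(" wt:", object@wt, "\n")
})

setMethod("show", "HostOracle", function(object) {
  cat(sprintf(
    "HostOracle: %d motifs (width %d), threshold = %.3g, gain = %.3g, %d hot subsequences\n",
    length(object@motifs),
    if (length(object@motifs)) nrow(object@motifs[[1L]]) else 0L,
    object@threshold, object@gain, length(object@hotSeqs)))
})

#' Wild-type sequence of an oracle
#' @param oracle An [OrthogonalOracle-class].
#' @return Character scalar.
#' @export
wildType <- function(oracle) oracle@wt

#' Sample a smooth orthogonal activity oracle
#'
#' Activity is `Tmax * exp(-beta * (sum_i penalty[i, s_i] + epistasis))`:
#' maximal at the wild type and non-increasing as mismatch penalties
#' accumulate. Per-position penalties are drawn once per seed from a
#' mixture of near-neutral and deleterious exponentials, with one
#' contiguous core window of strongly deleterious positions emulating the
#' conserved core motif of a phage promoter.
#'
#' @param L Sequence length (default 31, the core-promoter library length).
#' @param seed Integer seed; the oracle is a pure function of it.
#' @param wt Optional wild-type sequence; sampled uniformly if `NULL`.
#' @param Tmax Wild-type activity (default 100 units).
#' @param beta Smoothness coefficient (default 1).
#' @param coreStart First position (1-based) of the functional core
#'   window; `NA` centres it.
#' @param coreWidth Width of the functional core (default 12). Promoter
#'   activity of a monomeric phage polymerase is determined by its binding
#'   footprint: one contiguous localised window carries all the
#'   sequence-activity information, with a strongly conserved centre and
#'   graded shoulders, while flanking positions are near-neutral.
#' @param nPairs Number of pairwise epistatic penalties (default 0,
#'   purely additive).
#' @return An [OrthogonalOracle-class] object.
#' @export
sampleOrthogonalOracle <- function(L = 31L, seed = 1L, wt = NULL,
                                   Tmax = 100, beta = 1,
                                   coreStart = NA, coreWidth = 12L,
                                   nPairs = 0L) {
  if (L < 4L) stop("L must be >= 4")
  withSeed(seed, {
    if (is.null(wt)) wt <- paste(sample(DNA_BASES4, L, TRUE), collapse = "")
    wt <- checkDNA(wt)
    if (nchar(wt) != L) stop("wt length must equal L")
    wtIdx <- match(strsplit(wt, "")[[1L]], DNA_BASES4)
    coreWidth <- min(coreWidth, L)
    if (is.na(coreStart)) coreStart <- max(1L, (L - coreWidth) %/% 2L + 1L)
    core <- seq.int(coreStart, min(L, coreStart + coreWidth - 1L))
    centre <- core[core >= coreStart + (coreWidth - 5L) %/% 2L &
                     core < coreStart + (coreWidth - 5L) %/% 2L + 5L]
    pen <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES4))
    for (i in seq_len(L)) {
      alt <- setdiff(1:4, wtIdx[i])
      pen[i, alt] <- if (i %in% centre) 0.8 + stats::rexp(3L, rate = 2)
      else if (i %in% core) stats::rexp(3L, rate = 1.4)
      else stats::rexp(3L, rate = 50)
    }
    pairs <- matrix(numeric(0), 0L, 3L,
                    dimnames = list(NULL, c("i", "j", "penalty")))
    if (nPairs > 0L) {
      ij <- t(replicate(nPairs, sort(sample.int(L, 2L))))
      pairs <- cbind(ij, stats::rexp(nPairs, rate = 1))
      colnames(pairs) <- c("i", "j", "penalty")
    }
    new("OrthogonalOracle", wt = wt, penalty = pen, Tmax = Tmax,
        beta = beta, pairs = pairs)
  })
}

#' Sample a rugged host activity oracle
#'
#' Host activity is `gain * sum(max(0, window motif score - threshold))`
#' over all motif x window combinations, plus fixed boosts for exact
#' matches to a sparse set of "hot" subsequences. Thresholding creates
#' cliffs (local optima) and the hot set mimics cryptic host promoters
#' arising from random sequence. The threshold is raised, if necessary,
#' just above the wild type's best window score so the designated wild
#' type itself is host-silent (the premise of an insulated system).
#'
#' @param L Sequence length.
#' @param seed Integer seed.
#' @param wt Wild-type sequence kept host-silent (optional).
#' @param nMotifs Number of host motifs (default 3).
#' @param motifWidth Motif width (default 6).
#' @param threshold Base window-score threshold (default 2.5).
#' @param gain Linear gain (default 25).
#' @param nHot Number of hot subsequences (default 20).
#' @return A [HostOracle-class] object.
#' @export
sampleHostOracle <- function(L = 31L, seed = 2L, wt = NULL, nMotifs = 3L,
                             motifWidth = 6L, threshold = 2.5, gain = 25,
                             nHot = 20L) {
  withSeed(seed, {
    motifs <- replicate(nMotifs, {
      m <- matrix(stats::rnorm(motifWidth * 4L), motifWidth, 4L,
                  dimnames = list(NULL, DNA_BASES4))
      m
    }, simplify = FALSE)
    hot <- unique(replicate(nHot, paste(sample(DNA_BASES4, motifWidth, TRUE),
                                        collapse = "")))
    boost <- stats::runif(length(hot), 20, 80)
    oracle <- new("HostOracle", motifs = motifs, threshold = threshold,
                  gain = gain, hotSeqs = hot, hotBoost = boost)
    if (!is.null(wt)) {
      wt <- checkDNA(wt)
      keep <- !vapply(hot, function(h) grepl(h, wt, fixed = TRUE), logical(1))
      oracle@hotSeqs <- hot[keep]
      oracle@hotBoost <- boost[keep]
      s <- .hostWindowScores(oracle, wt)
      oracle@threshold <- max(threshold, max(s) + 0.5)
    }
    oracle
  })
}

# motif window scores for a batch: list (one per motif) of n x nWindows
.hostWindowScoreMatrix <- function(oracle, seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  idx <- matrix(match(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                      DNA_BASES4), nrow = n, ncol = L, byrow = TRUE)
  lapply(oracle@motifs, function(m) {
    k <- nrow(m)
    if (L < k) return(matrix(numeric(0), n, 0L))
    nw <- L - k + 1L
    sc <- matrix(0, n, nw)
    for (j in seq_len(k)) {
      cols <- j:(j + nw - 1L)
      sc <- sc + matrix(m[j, ][idx[, cols]], n, nw)
    }
    sc
  })
}

# window scores of all motifs over one sequence (vector over windows x motifs)
.hostWindowScores <- function(oracle, seq) {
  unlist(lapply(.hostWindowScoreMatrix(oracle, seq), as.vector))
}

#' Noise-free orthogonal ground-truth activity
#'
#' @param oracle An [OrthogonalOracle-class].
#' @param seqs Character vector of sequences of the oracle's length.
#' @return Numeric vector of activities (strictly positive).
#' @export
orthogonalActivity <- function(oracle, seqs) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  L <- nchar(oracle@wt)
  if (nchar(seqs[1L]) != L) stop("sequence length does not match oracle")
  n <- length(seqs)
  idx <- matrix(match(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                      DNA_BASES4), nrow = n, ncol = L, byrow = TRUE)
  pos <- matrix(seq_len(L), n, L, byrow = TRUE)
  tot <- rowSums(matrix(oracle@penalty[cbind(as.vector(pos),
                                             as.vector(idx))], n, L))
  if (nrow(oracle@pairs)) {
    wtIdx <- match(strsplit(oracle@wt, "")[[1L]], DNA_BASES4)
    mut <- idx != matrix(wtIdx, n, L, byrow = TRUE)
    for (r in seq_len(nrow(oracle@pairs))) {
      i <- oracle@pairs[r, 1L]; j <- oracle@pairs[r, 2L]
      tot <- tot + oracle@pairs[r, 3L] * (mut[, i] & mut[, j])
    }
  }
  unname(oracle@Tmax * exp(-oracle@beta * tot))
}

#' Noise-free host ground-truth activity
#'
#' @param oracle A [HostOracle-class].
#' @param seqs Character vector of sequences.
#' @return Numeric vector of activities (zero when no window exceeds the
#'   threshold and no hot subsequence matches).
#' @export
hostActivity <- function(oracle, seqs) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  n <- length(seqs)
  L <- nchar(seqs[1L])
  sc <- .hostWindowScoreMatrix(oracle, seqs)
  a <- numeric(n)
  for (m in sc)
    if (ncol(m)) {
      ex <- m - oracle@threshold
      ex[ex < 0] <- 0
      a <- a + rowSums(ex)
    }
  a <- oracle@gain * a
  if (length(oracle@hotSeqs)) {
    boost <- stats::setNames(oracle@hotBoost, oracle@hotSeqs)
    for (k in unique(nchar(oracle@hotSeqs))) {
      if (L < k) next
      for (p in seq_len(L - k + 1L)) {
        w <- substr(seqs, p, p + k - 1L)
        hit <- w %in% names(boost)
        if (any(hit)) a[hit] <- a[hit] + boost[w[hit]]
      }
    }
  }
  a
}

#' Simulate replicate activity measurements
#'
#' Induced measurements report host + orthogonal activity; uninduced
#' measurements report host activity only. Both are corrupted by
#' multiplicative lognormal noise and floored at the detection floor.
#'
#' @param seqs Character vector of sequences.
#' @param induced Logical: with (TRUE) or without (FALSE) induction of the
#'   orthogonal polymerase.
#' @param orth An [OrthogonalOracle-class].
#' @param host A [HostOracle-class].
#' @param mm A [MeasurementModel-class].
#' @param seed Integer seed.
#' @return Matrix of dimension `length(seqs)` x `mm@replicates`.
#' @export
measureActivity <- function(seqs, induced, orth, host, mm = MeasurementModel(),
                            seed = 1L) {
  mu <- hostActivity(host, seqs)
  if (induced) mu <- mu + orthogonalActivity(orth, seqs)
  withSeed(seed, {
    n <- length(mu); r <- mm@replicates
    noise <- if (mm@noiseSigma > 0)
      exp(matrix(stats::rnorm(n * r, 0, mm@noiseSigma), n, r)) else
      matrix(1, n, r)
    pmax(mu * noise, mm@floor)
  })
}

# count of sequences in the substitution ball of radius maxEdit (excluding wt)
.ballSize <- function(L, maxEdit) {
  sum(vapply(seq_len(maxEdit), function(k) choose(L, k) * 3^k, numeric(1)))
}

#' Generate a bounded-mutation library around a wild type
#'
#' Unique substitution mutants with edit count drawn uniformly from
#' `1..maxEdit` and uniformly random positions and alternate bases
#' (edit distance and Hamming distance coincide for such mutants).
#'
#' @param wt Wild-type sequence.
#' @param n Number of unique mutants requested.
#' @param maxEdit Maximum number of substitutions (default 8).
#' @param seed Integer seed.
#' @return Character vector of `n` unique sequences.
#' @export
generateMutantLibrary <- function(wt, n, maxEdit = 8L, seed = 1L) {
  wt <- checkDNA(wt)
  L <- nchar(wt)
  if (maxEdit < 1L) stop("maxEdit must be >= 1: no mutants exist otherwise")
  if (maxEdit > L) stop("maxEdit cannot exceed sequence length")
  if (n > .ballSize(L, maxEdit))
    stop("requested more unique mutants than exist within maxEdit")
  wtChars <- strsplit(wt, "")[[1L]]
  withSeed(seed, {
    out <- character(0)
    while (length(out) < n) {
      m <- n - length(out)
      batch <- vapply(seq_len(m), function(i) {
        k <- sample.int(maxEdit, 1L)
        posn <- sample.int(L, k)
        ch <- wtChars
        for (p in posn) ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1L)
        paste(ch, collapse = "")
      }, character(1))
      out <- unique(c(out, setdiff(batch, wt)))
    }
    out[seq_len(n)]
  })
}

#' Generate a uniform random sequence library
#'
#' @param n Number of sequences.
#' @param L Sequence length.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences (not necessarily unique).
#' @export
generateRandomLibrary <- function(n, L = 31L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  withSeed(seed, {
    vapply(seq_len(n),
           function(i) paste(sample(DNA_BASES4, L, TRUE), collapse = ""),
           character(1))
  })
}

#' Default synthetic-system configuration
#'
#' The defaults define the emulated study conditions: a 1252-sequence
#' library of 31-bp promoters within 8 substitutions of the wild type,
#' measured in triplicate under induced and uninduced conditions with
#' lognormal noise of sd 0.1 (at which the oracle explains well over 97%
#' of the variance of triplicate-averaged purified activities).
#'
#' @param seed Global seed; all per-stage seeds are derived from it.
#' @param ... Overrides for any configuration entry.
#' @return Named list of configuration values.
#' @export
defaultSystemConfig <- function(seed = 1L, ...) {
  cfg <- list(seed = seed, n = 1252L, L = 31L, maxEdit = 8L,
              replicates = 3L, noiseSigma = 0.1, floor = 0.1,
              Tmax = 100, beta = 1, nPairs = 0L,
              oracleSeedOffset = 11L, hostSeedOffset = 12L,
              librarySeedOffset = 13L, measureSeedOffset = 14L)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' @rdname SyntheticSystem-class
#' @slot records Activity `data.frame` (one row per promoter).
#' @slot orth The generating [OrthogonalOracle-class].
#' @slot host The generating [HostOracle-class].
#' @slot mm The [MeasurementModel-class] used.
#' @slot config The configuration list.
#' @export
setClass("SyntheticSystem",
  representation(records = "data.frame", orth = "OrthogonalOracle",
                 host = "HostOracle", mm = "MeasurementModel",
                 config = "list"))

setMethod("show", "SyntheticSystem", function(object) {
  cat(sprintf("SyntheticSystem: %d records of length %d (wt %s)\n",
              nrow(object@records), nchar(object@orth@wt), object@orth@wt))
})

#' Records of a synthetic system
#' @param system A [SyntheticSystem-class].
#' @return The activity `data.frame`.
#' @export
systemRecords <- function(system) system@records

#' Build the default synthetic training dataset
#'
#' Draws the oracles, generates the bounded-mutation library, simulates
#' triplicate induced and uninduced measurements, and stores their means in
#' the `induced` / `uninduced` columns. The `purified` column is left `NA`;
#' it is filled by the purification pipeline.
#'
#' @param config Configuration list from [defaultSystemConfig()].
#' @return A [SyntheticSystem-class] object.
#' @export
buildTrainingDataset <- function(config = defaultSystemConfig()) {
  orth <- sampleOrthogonalOracle(L = config$L,
                                 seed = childSeed(config$seed,
                                                  config$oracleSeedOffset),
                                 Tmax = config$Tmax, beta = config$beta,
                                 nPairs = config$nPairs)
  host <- sampleHostOracle(L = config$L,
                           seed = childSeed(config$seed,
                                            config$hostSeedOffset),
                           wt = orth@wt)
  mm <- MeasurementModel(noiseSigma = config$noiseSigma,
                         floor = config$floor,
                         replicates = config$replicates)
  seqs <- generateMutantLibrary(orth@wt, config$n, config$maxEdit,
                                seed = childSeed(config$seed,
                                                 config$librarySeedOffset))
  mi <- measureActivity(seqs, TRUE, orth, host, mm,
                        seed = childSeed(config$seed,
                                         config$measureSeedOffset))
  mu <- measureActivity(seqs, FALSE, orth, host, mm,
                        seed = childSeed(config$seed,
                                         config$measureSeedOffset + 1L))
  rec <- data.frame(id = sprintf("mut%04d", seq_along(seqs)),
                    sequence = seqs,
                    induced = rowMeans(mi),
                    uninduced = rowMeans(mu),
                    purified = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(mm@replicates)) {
    rec[[sprintf("rep%d_induced", r)]] <- mi[, r]
    rec[[sprintf("rep%d_uninduced", r)]] <- mu[, r]
  }
  new("SyntheticSystem", records = rec, orth = orth, host = host, mm = mm,
      config = config)
}

#' Count strict local optima of an activity function by full enumeration
#'
#' Enumerates all `4^L` sequences and counts those whose activity is no
#' lower than every single-substitution neighbour and strictly higher than
#' at least one (so flat plateaus are not counted wholesale). Used to make
#' the ruggedness comparison between the host and orthogonal landscapes
#' testable.
#'
#' @param activityFun Function mapping a character vector of sequences to
#'   activities.
#' @param L Sequence length (capped at 8 to keep enumeration tractable).
#' @return Integer count of local optima.
#' @export
countLocalOptima <- function(activityFun, L) {
  if (L > 8L) stop("full enumeration is limited to L <= 8")
  n <- 4L^L
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  seqs <- apply(grid, 1L, function(r) paste(DNA_BASES4[r], collapse = ""))
  act <- activityFun(seqs)
  pow <- 4L^(seq_len(L) - 1L)
  isOpt <- rep(TRUE, n)
  hasStrict <- rep(FALSE, n)
  idx0 <- as.integer((grid - 1L) %*% pow)  # 0-based index of each sequence
  for (i in seq_len(L)) {
    for (delta in 1:3) {
      nb <- idx0 + ((grid[, i] - 1L + delta) %% 4L - (grid[, i] - 1L)) * pow[i]
      nbAct <- act[nb + 1L]
      isOpt <- isOpt & (act >= nbAct)
      hasStrict <- hasStrict | (act > nbAct)
    }
  }
  sum(isOpt & hasStrict)
}
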