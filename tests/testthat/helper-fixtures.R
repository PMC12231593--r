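# Shared fixtures, trained once per test run and memoised.
#
# The "full" fixtures reproduce the default study conditions (1252 records
# of 31 bp, triplicate, low noise) and the three predictor roles; the
# "small" fixtures are reduced-scale versions for property tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fixtureSystem <- function() memo("system", buildTrainingDataset(
  defaultSystemConfig(1L)))

# full dataset with the purified column filled by host subtraction
fixtureRecords <- function() memo("records", {
  step3Subtract(systemRecords(fixtureSystem()))$records
})

fixtureOrthPredictor <- function() memo("orth", trainPredictor(
  fixtureRecords(), "orthogonal", split = "90/10", seed = 11L))

fixtureHostPredictor <- function() memo("host", trainPredictor(
  fixtureRecords(), "host", split = "90/10", seed = 12L))

fixtureMixedPredictor <- function() memo("mixed", trainPredictor(
  fixtureRecords(), "mixed", split = "90/10", seed = 13L))

# the default de novo design batch against the full fixtures (heavy; the
# acceptance blocks for design counts and for purification benefit share it)
fixtureDeNovo <- function() memo("denovo", batchDeNovo(
  fixtureOrthPredictor(), fixtureHostPredictor(),
  cfg = designConfig(seed = 21L), wt = wildType(fixtureSystem()@orth)))

# reduced-scale system (for multi-seed property tests)
fixtureSmallSystem <- function(seed = 5L) {
  memo(paste0("smallsys", seed),
       buildTrainingDataset(defaultSystemConfig(seed, n = 250L)))
}

fixtureSmallRecords <- function(seed = 5L) {
  memo(paste0("smallrec", seed),
       step3Subtract(systemRecords(fixtureSmallSystem(seed)))$records)
}

# a linear-response predictor with hand-set dense weights: activity is an
# explicit linear function of the one-hot encoding, so tests can enumerate
# ground truth independently of any training
makeLinearToyPredictor <- function(W, intercept = 0, L = nrow(W)) {
  stopifnot(ncol(W) == 4L)
  model <- nnBuild("linear", L = L, seed = 1L)
  model$layers$dense$W <- matrix(as.vector(W), ncol = 1L)
  model$layers$dense$b <- intercept
  new("TrainedPredictor", model = model, role = "orthogonal",
      responseScale = "linear", yCenter = 0, yScale = 1,
      split = list(), metrics = list())
}

# a predictor that always answers `value` (useful as a null host model)
makeConstantPredictor <- function(value, L, role = "host") {
  model <- nnBuild("linear", L = L, seed = 1L)
  model$layers$dense$W <- matrix(0, 4L * L, 1L)
  model$layers$dense$b <- value
  new("TrainedPredictor", model = model, role = role,
      responseScale = "linear", yCenter = 0, yScale = 1,
      split = list(), metrics = list())
}

# brute-force Hamming over all pairs (independent of minPairwiseHamming)
bruteMinPairwise <- function(seqs) {
  n <- length(seqs)
  best <- nchar(seqs[1L])
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      best <- min(best, sum(strsplit(seqs[i], "")[[1L]] !=
                              strsplit(seqs[j], "")[[1L]]))
  best
}

# dynamic-programming edit distance (independent oracle for hammingDist)
editDistanceDP <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  d <- matrix(0, length(A) + 1L, length(B) + 1L)
  d[, 1L] <- 0:length(A); d[1L, ] <- 0:length(B)
  for (i in seq_along(A))
    for (j in seq_along(B))
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (A[i] != B[j]))
  d[length(A) + 1L, length(B) + 1L]
}

randomSeqs <- function(n, L, seed) generateRandomLibrary(n, L, seed)

# finite-difference input-gradient check shared by engine and acceptance tests
fdInputCheck <- function(arch, L = 12L, nCells = 10L, seed = 3L) {
  m <- nnBuild(arch, L = L, seed = seed)
  withr::with_seed(seed, {
    X <- array(rnorm(2 * L * 4, sd = 0.5) + 0.25, c(2, L, 4))
    w <- c(1, 0.5)
    fb <- if (arch == "cnn") {
      g <- orthodesign:::.cnnGradCpp(X, m$layers, w, TRUE)
      list(dX = g$dX,
           val = function(Xm) sum(orthodesign:::.cnnForwardCpp(
             Xm, m$layers)$pred * w))
    } else {
      fw <- orthodesign:::nnForward(m, X)
      bw <- orthodesign:::nnBackward(m, fw$cache, w)
      list(dX = bw$dX,
           val = function(Xm) sum(orthodesign:::nnForward(m, Xm)$pred * w))
    }
    errs <- vapply(seq_len(nCells), function(i) {
      b <- sample(2, 1); p <- sample(L, 1); ch <- sample(4, 1)
      eps <- 1e-5
      Xp <- X; Xp[b, p, ch] <- X[b, p, ch] + eps
      Xm2 <- X; Xm2[b, p, ch] <- X[b, p, ch] - eps
      fd <- (fb$val(Xp) - fb$val(Xm2)) / (2 * eps)
      abs(fd - fb$dX[b, p, ch]) / max(1e-8, abs(fd))
    }, numeric(1))
    max(errs)
  })
}
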