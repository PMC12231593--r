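test_that("relaxed predictions agree with the sequence path on hard encodings", {
  p <- fixtureOrthPredictor()
  seqs <- randomSeqs(5, 31, seed = 14)
  direct <- predictActivity(p, seqs)
  for (i in seq_along(seqs)) {
    rel <- predictRelaxed(p, encodeOneHot(seqs[i]))
    expect_equal(rel$activity, direct[i], tolerance = 1e-10)
    expect_equal(dim(rel$gradient), c(31, 4))
  }
  # all-zero relaxed encoding: out of distribution but finite
  zero <- predictRelaxed(p, matrix(0, 31, 4))
  expect_true(is.finite(zero$activity))
  expect_true(all(is.finite(zero$gradient)))
})

test_that("relaxed gradients match finite differences through the response transform", {
  p <- fixtureOrthPredictor()
  enc <- encodeOneHot(randomSeqs(1, 31, seed = 3))
  g <- predictRelaxed(p, enc)
  withr::with_seed(5, {
    for (k in 1:8) {
      i <- sample(31, 1); j <- sample(4, 1)
      eps <- 1e-5
      up <- enc; up[i, j] <- up[i, j] + eps
      dn <- enc; dn[i, j] <- dn[i, j] - eps
      fd <- (predictRelaxed(p, up)$activity -
               predictRelaxed(p, dn)$activity) / (2 * eps)
      expect_lt(abs(fd - g$gradient[i, j]) / max(1e-6, abs(fd)), 1e-3)
    }
  })
})

test_that("evaluation metrics match a textbook two-pass computation", {
  W <- matrix(rnorm(31 * 4, sd = 0.1), 31, 4)
  p <- makeLinearToyPredictor(W, intercept = 5)
  seqs <- randomSeqs(40, 31, seed = 8)
  pred <- predictActivity(p, seqs)
  # targets equal to the predictions: perfect scores
  rec <- data.frame(id = seq_along(seqs), sequence = seqs,
                    purified = pmax(0, pred))
  ev <- evaluatePredictor(p, rec)
  expect_equal(ev$R2, 1, tolerance = 1e-9)
  expect_lt(ev$mse, 1e-18)
  # anti-correlated targets
  rec$purified <- max(pred) + min(pred) - pred
  expect_equal(evaluatePredictor(p, rec)$pearsonR, -1, tolerance = 1e-9)
  # R^2 equals the square of the explicit covariance formula
  withr::with_seed(2, rec$purified <- abs(pred + rnorm(40, sd = 2)))
  ev <- evaluatePredictor(p, rec)
  x <- predictActivity(p, rec$sequence); y <- rec$purified
  manual <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(ev$pearsonR, manual, tolerance = 1e-9)
  expect_equal(ev$R2, manual^2, tolerance = 1e-9)
  expect_error(evaluatePredictor(p, rec[1:2, ]), "at least 3")
})

test_that("a constant-activity dataset is handled as a degenerate target", {
  rec <- data.frame(id = 1:40, sequence = randomSeqs(40, 31, seed = 6),
                    purified = rep(7, 40), induced = rep(7, 40),
                    uninduced = rep(0, 40))
  p <- trainPredictor(rec, "orthogonal", arch = "linear", epochs = 3L,
                      seed = 1L)
  expect_true(isTRUE(p@metrics$constantTarget) ||
                isTRUE(p@metrics$degenerate) || is.na(p@metrics$R2))
})

test_that("the linear baseline recovers an additive noise-free landscape", {
  sys <- buildTrainingDataset(defaultSystemConfig(4, n = 400L,
                                                  replicates = 1L,
                                                  noiseSigma = 0,
                                                  floor = 0))
  rec <- step3Subtract(systemRecords(sys))$records
  p <- trainPredictor(rec, "orthogonal", arch = "linear", split = "80/10/10",
                      epochs = 2000L, patience = 300L, seed = 2L)
  expect_gte(p@metrics$R2, 0.95)
})

test_that("training splits are disjoint, exhaustive and seeded", {
  sp <- orthodesign:::.makeSplit(100, orthodesign:::.parseSplit("80/10/10"),
                                 seed = 4)
  expect_length(c(sp$train, sp$val, sp$test), 100)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:100)
  expect_length(sp$test, 10)
  sp2 <- orthodesign:::.makeSplit(100, orthodesign:::.parseSplit("90/10"),
                                  seed = 4)
  expect_length(sp2$test, 10)
  expect_gt(length(sp2$val), 0)    # checkpointing carve-out
  expect_identical(sp2,
                   orthodesign:::.makeSplit(100,
                                            orthodesign:::.parseSplit("90/10"),
                                            seed = 4))
  expect_error(orthodesign:::.parseSplit("70/30"), NA)
  expect_error(orthodesign:::.parseSplit("80/15"), "split")
})

test_that("the default CNN reaches the headline held-out accuracy", {
  p <- fixtureOrthPredictor()
  expect_gte(p@metrics$R2, 0.90)
  expect_equal(p@metrics$R2, p@metrics$pearsonR^2, tolerance = 1e-12)
})

test_that("predictions are deterministic given a trained model", {
  p <- fixtureOrthPredictor()
  seqs <- randomSeqs(10, 31, seed = 1)
  expect_identical(predictActivity(p, seqs), predictActivity(p, seqs))
})
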