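# Design machinery. Heavier end-to-end runs live in test-acceptance.R;
# these tests exercise selection logic, constraint soundness and the
# gradient designer on enumerable toys.

test_that("level menus carry the documented totals and allocations", {
  sr <- semiRationalLevels()
  expect_equal(sum(sr$count), 58)
  expect_equal(sr$level[1], 1)
  expect_length(sr$level, 8)
  dn <- deNovoLevels()
  expect_equal(sum(dn$count), 41)
  expect_length(dn$level, 11)
  expect_equal(max(dn$level), 5 / 4)
})

test_that("greedy level selection picks the pool optimum when it is available", {
  # a pool that contains the wild type itself: the level-1 pick must be the
  # wild type (or an equal-predicted sequence)
  W <- matrix(0, 8, 4)
  W[2, ] <- c(0, -3, -4, -5)    # position 2: A best
  W[5, ] <- c(-2, 0, -1, -4)
  p <- makeLinearToyPredictor(W, intercept = 10, L = 8)
  wt <- "AAAACAAA"              # optimal under W
  pool <- c(wt, generateMutantLibrary(wt, 200, 3, seed = 2))
  pred <- predictActivity(p, pool)
  pick <- orthodesign:::.greedyPick(pool, pred, max(pred), 1L,
                                    character(0), 0L)
  expect_equal(pred[pick], max(pred))
})

test_that("greedy picks respect the pairwise distance floor and tie-break by distance", {
  seqs <- c("AAAAAAAA", "AAAAAAAT", "TTTTAAAA", "TTTTTTTT")
  pred <- c(10, 10, 10, 10)
  pick <- orthodesign:::.greedyPick(seqs, pred, 10, 3L, character(0), 4L)
  got <- seqs[pick]
  expect_gte(bruteMinPairwise(got), 4)
  expect_lte(length(pick), 3)
})

test_that("farthest-point selection matches exhaustive max-min search on a 30-candidate pool", {
  combs <- utils::combn(30L, 3L)
  for (sd in c(44, 45, 46)) {
    cand <- randomSeqs(30, 12, seed = sd)
    picked <- orthodesign:::.farthestPointPick(cand, rep(10, 30), 10, 3L)
    got <- minPairwiseHamming(cand[picked])
    bestMinD <- max(apply(combs, 2L, function(ix)
      minPairwiseHamming(cand[ix])))
    expect_identical(got, bestMinD)
  }
})

test_that("fixed-level sets respect the predicted spread bound", {
  p <- fixtureOrthPredictor()
  wt <- wildType(fixtureSystem()@orth)
  fx <- fixedLevelDiverse(p, wt, level = 1 / 16, n = 12L,
                          cfg = designConfig(seed = 3))
  d <- designRecords(fx)
  expect_identical(nrow(d), 12L)
  expect_lte(max(d$predicted) / min(d$predicted), 1.51)
  one <- fixedLevelDiverse(p, wt, level = 1 / 16, n = 1L,
                           cfg = designConfig(seed = 3))
  # n = 1: the single candidate nearest the level
  target <- predictActivity(p, wt) / 16
  expect_lte(abs(designRecords(one)$predicted - target),
             min(abs(d$predicted - target)) + 1e-9)
})

test_that("semi-rational design is deterministic given the configuration", {
  p <- fixtureOrthPredictor()
  h <- fixtureHostPredictor()
  wt <- wildType(fixtureSystem()@orth)
  cfg <- designConfig(seed = 9, poolSize = 1500L)
  t1 <- semiRational(p, h, wt, targets = data.frame(level = c(1, 1 / 4),
                                                    count = c(3L, 3L)),
                     cfg = cfg)
  t2 <- semiRational(p, h, wt, targets = data.frame(level = c(1, 1 / 4),
                                                    count = c(3L, 3L)),
                     cfg = cfg)
  expect_identical(designRecords(t1), designRecords(t2))
})

test_that("a start already at the target terminates immediately", {
  W <- matrix(0, 8, 4)
  p <- makeLinearToyPredictor(W, intercept = 20, L = 8)   # constant 20
  h <- makeConstantPredictor(0, 8L)
  res <- deNovoDesign(p, h, targetLevel = 1,
                      cfg = designConfig(seed = 2, climbIters = 0L),
                      Tref = 20)
  expect_identical(nrow(res$trajectory@steps), 1L)
  expect_identical(res$trajectory@steps$step, 0L)
})

test_that("the returned design is the best decoded point of its trajectory", {
  p <- fixtureOrthPredictor()
  h <- fixtureHostPredictor()
  wt <- wildType(fixtureSystem()@orth)
  # with smoothed harvesting disabled the returned design minimises the
  # point closeness to the target over all recorded steps
  res <- deNovoDesign(p, h, targetLevel = 1 / 4,
                      cfg = designConfig(seed = 4, maxIters = 120L,
                                         climbIters = 0L,
                                         smoothEvery = 10000L),
                      wt = wt)
  steps <- res$trajectory@steps
  target <- res$trajectory@target
  closeness <- abs(steps$predicted - target) +
    ifelse(steps$predictedHost >= 10, Inf, 0)
  best <- steps[res$trajectory@best, ]
  expect_equal(abs(best$predicted - target), min(closeness))
  expect_true(res$sequence %in% steps$sequence)
})

test_that("emitted design sets satisfy their recorded constraints independently", {
  p <- fixtureOrthPredictor()
  h <- fixtureHostPredictor()
  wt <- wildType(fixtureSystem()@orth)
  dn <- batchDeNovo(p, h, targets = data.frame(level = c(1 / 2, 1 / 8),
                                               count = c(3L, 3L)),
                    cfg = designConfig(seed = 6, maxIters = 400L,
                                       climbIters = 150L),
                    wt = wt)
  d <- designRecords(dn)
  expect_identical(nrow(d), 6L)
  expect_false(anyDuplicated(d$sequence) > 0)
  # constraint soundness checked independently of the designer
  expect_true(all(predictActivity(h, d$sequence) < dn@constraints$tau1))
  expect_equal(hammingToAll(wt, d$sequence), d$hammingToWT,
               ignore_attr = TRUE)
  # reported predictions are either the neighbourhood-median (smoothed)
  # model prediction or, for designs that never reached a harvest
  # window, the raw model prediction; recompute both independently
  for (i in c(1L, 4L)) {
    nb <- c(d$sequence[i],
            orthodesign:::.allSingleMutants(d$sequence[i]))
    sm <- median(predictActivity(p, nb))
    pt <- predictActivity(p, d$sequence[i])
    expect_true(isTRUE(all.equal(d$predicted[i], sm, tolerance = 1e-6)) ||
                  isTRUE(all.equal(d$predicted[i], pt, tolerance = 1e-6)))
  }
})

test_that("design sets export losslessly to FASTA and TSV", {
  p <- fixtureOrthPredictor()
  wt <- wildType(fixtureSystem()@orth)
  fx <- fixedLevelDiverse(p, wt, level = 1 / 16, n = 4L,
                          cfg = designConfig(seed = 3))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDesignSet(fx, fa, tsv)
  expect_identical(unname(readFastaSeqs(fa)), designRecords(fx)$sequence)
  back <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$predicted, designRecords(fx)$predicted,
               tolerance = 1e-9)
})

test_that("oracle-wrapped validation is perfectly self-consistent", {
  # a predictor that IS the oracle: R^2 = 1 under noise-free measurement
  sys <- buildTrainingDataset(defaultSystemConfig(15, n = 50L))
  seqs <- systemRecords(sys)$sequence[1:20]
  d <- data.frame(id = as.character(1:20), sequence = seqs,
                  targetLevel = 1,
                  predicted = orthogonalActivity(sys@orth, seqs),
                  predictedHost = 0, hammingToWT = 0L,
                  provenance = "de_novo", converged = TRUE,
                  stringsAsFactors = FALSE)
  set <- new("DesignSet", designs = d, wt = wildType(sys@orth),
             config = designConfig(), constraints = list())
  mm0 <- MeasurementModel(noiseSigma = 0, floor = 0, replicates = 1L)
  v <- validateDesigns(set, sys@orth, sys@host, mm0, seed = 1)
  expect_equal(v$R2, 1, tolerance = 1e-12)
  expect_equal(v$evaluated, d$predicted)
})
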