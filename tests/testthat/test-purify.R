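test_that("step I keeps everything at an infinite threshold and nothing at zero", {
  seqs <- randomSeqs(30, 31, seed = 2)
  host <- makeConstantPredictor(5, 31L)       # strictly positive outputs
  all <- step1FilterHost(seqs, host, Inf)
  expect_length(all$retained, 30)
  none <- step1FilterHost(seqs, host, 0)
  expect_length(none$retained, 0)
  expect_length(none$removed, 30)
})

test_that("step I retains sequences within the predictor's error of the threshold", {
  host <- fixtureHostPredictor()
  sys <- fixtureSystem()
  rec <- systemRecords(sys)
  s1 <- step1FilterHost(rec$sequence, host, tau1 = 10)
  trueHost <- hostActivity(sys@host, rec$sequence[s1$retained])
  # retained sequences' true host activity is below the threshold plus the
  # predictor's largest error on this library
  err <- max(abs(predictActivity(host, rec$sequence) -
                   hostActivity(sys@host, rec$sequence)))
  expect_true(all(trueHost < 10 + err + 1e-9))
})

test_that("step II applies the pseudo-counted fold-change rule exactly", {
  rec <- data.frame(id = 1:3, sequence = randomSeqs(3, 31, seed = 1),
                    induced = c(10, 100, 1), uninduced = c(10, 20, 4))
  s2 <- step2FilterNonresponsive(rec, foldTau = 2, eps = 1)
  expect_identical(s2$retained, 2L)         # (100+1)/(20+1) ~ 4.8
  expect_identical(s2$removed, c(1L, 3L))   # ratio 1 and 0.4
  expect_equal(s2$ratio, c(11 / 11, 101 / 21, 2 / 5))
  rec$induced[1] <- -1
  expect_error(step2FilterNonresponsive(rec), "non-negative")
})

test_that("on noise-free data step II removes exactly the host-only promoters", {
  sys <- buildTrainingDataset(defaultSystemConfig(9, n = 200L,
                                                  replicates = 1L,
                                                  noiseSigma = 0,
                                                  floor = 0))
  rec <- systemRecords(sys)
  s2 <- step2FilterNonresponsive(rec, foldTau = 2, eps = 1)
  orth <- orthogonalActivity(sys@orth, rec$sequence)
  host <- hostActivity(sys@host, rec$sequence)
  # algebra of the rule: removed <=> orthogonal < (foldTau-1)*(host+eps)
  expect_identical(sort(s2$removed),
                   sort(which(orth < (2 - 1) * (host + 1))))
})

test_that("step III subtracts, floors at zero and logs the floored count", {
  rec <- data.frame(id = 1:2, sequence = randomSeqs(2, 31, seed = 3),
                    induced = c(100, 5), uninduced = c(20, 8))
  s3 <- step3Subtract(rec)
  expect_equal(s3$records$purified, c(80, 0))
  expect_identical(s3$floored, 1L)
})

test_that("noise-free purification reproduces the orthogonal oracle exactly", {
  sys <- buildTrainingDataset(defaultSystemConfig(10, n = 150L,
                                                  replicates = 1L,
                                                  noiseSigma = 0,
                                                  floor = 0))
  s3 <- step3Subtract(systemRecords(sys))
  expect_equal(s3$records$purified,
               orthogonalActivity(sys@orth, s3$records$sequence))
  expect_identical(s3$floored, 0L)
})

test_that("the full pipeline conserves records and reports consistent counts", {
  sys <- fixtureSystem()
  host <- fixtureHostPredictor()
  res <- runPurification(systemRecords(sys), host, tau1 = 10, foldTau = 2)
  rep <- res$report
  n <- nrow(systemRecords(sys))
  expect_identical(rep@removedStep1 + rep@removedStep2 + rep@retained, n)
  expect_identical(length(rep@flags), n)
  expect_identical(sum(rep@flags == "retained"), rep@retained)
  expect_identical(nrow(res$records), rep@retained)
  expect_true(all(!is.na(res$records$purified)))
  js <- jsonlite::fromJSON(purificationReportJSON(rep))
  expect_identical(js$retained, rep@retained)
})

test_that("raising the thresholds never increases the retained count", {
  sys <- fixtureSystem()
  host <- fixtureHostPredictor()
  rec <- systemRecords(sys)
  r1 <- runPurification(rec, host, tau1 = 50, foldTau = 1.5)
  r2 <- runPurification(rec, host, tau1 = 10, foldTau = 1.5)
  r3 <- runPurification(rec, host, tau1 = 10, foldTau = 3)
  expect_lte(r2$report@retained, r1$report@retained)
  expect_lte(r3$report@retained, r2$report@retained)
})

test_that("with the host oracle disabled step II removes almost nothing", {
  cfg <- defaultSystemConfig(12, n = 200L)
  sys <- buildTrainingDataset(cfg)
  silentHost <- new("HostOracle", motifs = sys@host@motifs,
                    threshold = Inf, gain = 0,
                    hotSeqs = character(0), hotBoost = numeric(0))
  mi <- measureActivity(systemRecords(sys)$sequence, TRUE, sys@orth,
                        silentHost, sys@mm, seed = 21)
  mu <- measureActivity(systemRecords(sys)$sequence, FALSE, sys@orth,
                        silentHost, sys@mm, seed = 22)
  rec <- systemRecords(sys)
  rec$induced <- rowMeans(mi); rec$uninduced <- rowMeans(mu)
  s2 <- step2FilterNonresponsive(rec, foldTau = 2, eps = 1)
  # every record is responsive by construction; only floor-level
  # activities can fail the pseudo-counted ratio
  expect_lt(length(s2$removed) / nrow(rec), 0.1)
  expect_true(all(orthogonalActivity(sys@orth,
                                     rec$sequence[s2$removed]) < 5))
})

test_that("purified activities train a better model than induced activities", {
  pOrth <- fixtureOrthPredictor()
  pMix <- fixtureMixedPredictor()
  expect_gt(pOrth@metrics$R2, pMix@metrics$R2)
})
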