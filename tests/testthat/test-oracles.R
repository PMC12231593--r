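test_that("orthogonal oracle is maximal at the wild type and matches its closed form", {
  orth <- sampleOrthogonalOracle(L = 6, seed = 21, coreStart = 2,
                                 coreWidth = 3)
  wt <- wildType(orth)
  expect_equal(orthogonalActivity(orth, wt), orth@Tmax)
  # every single mutant: activity from the penalty matrix by independent
  # arithmetic, and never above Tmax
  bases <- c("A", "C", "G", "T")
  wtCh <- strsplit(wt, "")[[1]]
  for (pos in 1:6) {
    for (b in setdiff(bases, wtCh[pos])) {
      mut <- wtCh; mut[pos] <- b
      a <- orthogonalActivity(orth, paste(mut, collapse = ""))
      manual <- unname(orth@Tmax * exp(-orth@beta * orth@penalty[pos, b]))
      expect_equal(a, manual, tolerance = 1e-12)
      expect_lte(a, orth@Tmax)
    }
  }
})

test_that("orthogonal activity is monotone non-increasing under extra mutations", {
  orth <- sampleOrthogonalOracle(L = 10, seed = 3, coreWidth = 4)
  wt <- wildType(orth)
  wtCh <- strsplit(wt, "")[[1]]
  bases <- c("A", "C", "G", "T")
  muts1 <- generateMutantLibrary(wt, 20, 1, seed = 5)
  for (m1 in muts1) {
    a1 <- orthogonalActivity(orth, m1)
    ch <- strsplit(m1, "")[[1]]
    p <- which(ch != wtCh)
    for (q in setdiff(1:10, p)) {
      ch2 <- ch
      ch2[q] <- setdiff(bases, ch[q])[1]
      expect_lte(orthogonalActivity(orth, paste(ch2, collapse = "")),
                 a1 + 1e-12)
    }
  }
})

test_that("host activity is zero without above-threshold windows or hot matches", {
  host <- new("HostOracle",
              motifs = list(matrix(0.1, 3, 4,
                                   dimnames = list(NULL,
                                                   c("A", "C", "G", "T")))),
              threshold = 10, gain = 5, hotSeqs = "GGG", hotBoost = 40)
  expect_equal(hostActivity(host, "AACTACT"), 0)
  expect_equal(hostActivity(host, "AAGGGTT"), 40)   # one hot match
  host2 <- new("HostOracle", motifs = host@motifs, threshold = 0.25,
               gain = 5, hotSeqs = character(0), hotBoost = numeric(0))
  # every window scores 0.3: excess 0.05 per window, 5 windows
  expect_equal(hostActivity(host2, "AACTACT"), 5 * 5 * 0.05)
})

test_that("host landscape is more rugged than the orthogonal one (exhaustive L = 6)", {
  orth <- sampleOrthogonalOracle(L = 6, seed = 21, coreStart = 2,
                                 coreWidth = 3)
  host <- sampleHostOracle(L = 6, seed = 22, nMotifs = 2, motifWidth = 3,
                           threshold = 1.5, nHot = 6)
  nOrth <- countLocalOptima(function(s) orthogonalActivity(orth, s), 6)
  nHost <- countLocalOptima(function(s) hostActivity(host, s), 6)
  expect_identical(nOrth, 1L)     # additive landscape: unique optimum
  expect_gt(nHost, nOrth)
})

test_that("measurement model is additive and exact without noise", {
  orth <- sampleOrthogonalOracle(L = 12, seed = 7)
  host <- sampleHostOracle(L = 12, seed = 8)
  mm0 <- MeasurementModel(noiseSigma = 0, floor = 0, replicates = 1L)
  seqs <- generateMutantLibrary(wildType(orth), 25, 4, seed = 2)
  mi <- measureActivity(seqs, TRUE, orth, host, mm0, seed = 1)
  mu <- measureActivity(seqs, FALSE, orth, host, mm0, seed = 1)
  expect_equal(mi[, 1] - mu[, 1], orthogonalActivity(orth, seqs))
  expect_equal(mu[, 1], hostActivity(host, seqs))
})

test_that("replicate noise is multiplicative lognormal with the expected mean", {
  orth <- sampleOrthogonalOracle(L = 8, seed = 7)
  host <- sampleHostOracle(L = 8, seed = 8)
  mm <- MeasurementModel(noiseSigma = 0.1, floor = 0, replicates = 10000L)
  wt <- wildType(orth)
  m <- measureActivity(wt, TRUE, orth, host, mm, seed = 3)
  noiseFree <- hostActivity(host, wt) + orthogonalActivity(orth, wt)
  # lognormal mean correction: E[X] = mu * exp(sigma^2 / 2)
  expect_equal(mean(m), noiseFree * exp(0.1^2 / 2), tolerance = 0.02)
})

test_that("mutant libraries are unique, within the edit bound, and seeded", {
  wt <- strrep("ACGT", 8)          # length 32
  lib <- generateMutantLibrary(wt, 500, 8, seed = 3)
  expect_equal(length(unique(lib)), 500)
  d <- vapply(lib, hammingDist, integer(1), a = wt)
  expect_true(all(d >= 1 & d <= 8))
  expect_identical(lib, generateMutantLibrary(wt, 500, 8, seed = 3))
  expect_error(generateMutantLibrary(wt, 10, 0), "maxEdit")
  # the full 1-ball of a length-4 sequence is exactly the 12 single mutants
  ball <- generateMutantLibrary("ACGT", 12, 1, seed = 1)
  expect_setequal(ball, unlist(lapply(1:4, function(p) {
    vapply(setdiff(c("A", "C", "G", "T"),
                   substr("ACGT", p, p)), function(b) {
      s <- strsplit("ACGT", "")[[1]]; s[p] <- b
      paste(s, collapse = "")
    }, character(1))
  })))
  expect_error(generateMutantLibrary("ACGT", 13, 1, seed = 1),
               "more unique mutants")
})

test_that("random libraries are uniform and reproducible", {
  lib <- generateRandomLibrary(10000, 31, seed = 5)
  expect_identical(lib, generateRandomLibrary(10000, 31, seed = 5))
  counts <- table(factor(unlist(strsplit(lib[1:2000], "")),
                         c("A", "C", "G", "T")))
  n <- sum(counts)
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(counts / n - 0.25) < 3 * se + 0.01))
  expect_length(generateRandomLibrary(1, 13, seed = 1), 1)
})

test_that("the default dataset matches the study conditions", {
  sys <- fixtureSystem()
  r <- systemRecords(sys)
  expect_identical(nrow(r), 1252L)
  expect_true(all(nchar(r$sequence) == 31L))
  expect_true(all(r$induced >= 0 & r$uninduced >= 0))
  expect_true(all(is.na(r$purified)))
  expect_identical(ncol(r), 5L + 6L)    # 3 replicate pairs
  # the oracle explains nearly all variance of triplicate-averaged
  # purified activities at the default noise level
  pur <- pmax(0, r$induced - r$uninduced)
  oracle <- orthogonalActivity(sys@orth, r$sequence)
  expect_gte(cor(pur, oracle)^2, 0.97)
})

test_that("a noise-free single-replicate dataset reproduces the oracle exactly", {
  sys <- buildTrainingDataset(defaultSystemConfig(3, n = 60L,
                                                  replicates = 1L,
                                                  noiseSigma = 0,
                                                  floor = 0))
  r <- systemRecords(sys)
  expect_equal(r$induced - r$uninduced,
               orthogonalActivity(sys@orth, r$sequence))
})

test_that("median purified activity decreases across hamming-distance bins", {
  sys <- fixtureSystem()
  r <- systemRecords(sys)
  pur <- pmax(0, r$induced - r$uninduced)
  d <- hammingToAll(wildType(sys@orth), r$sequence)
  med <- tapply(pur, d, median)
  bins <- as.integer(names(med))
  expect_lt(cor(bins, med, method = "spearman"), -0.7)
  expect_gt(med[["1"]], med[["8"]])
})

test_that("host activity dominates the top of a random library", {
  sys <- fixtureSystem()
  lib <- generateRandomLibrary(5000, 31, seed = 17)
  h <- hostActivity(sys@host, lib)
  o <- orthogonalActivity(sys@orth, lib)
  top <- order(h, decreasing = TRUE)[seq_len(50)]    # top 1%
  expect_lt(mean(o[top] > 0.05 * sys@orth@Tmax), 0.01)
})
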