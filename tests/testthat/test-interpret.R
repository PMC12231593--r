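test_that("penultimate feature maps are deterministic, non-negative and correctly shaped", {
  p <- fixtureOrthPredictor()
  seqs <- randomSeqs(6, 31, seed = 2)
  f <- penultimateFeatures(p, c(seqs, seqs[1]))
  expect_equal(dim(f), c(7, 15, 5))      # traced post-conv length before pooling
  expect_true(all(f >= 0))               # post-ReLU
  expect_equal(f[1, , ], f[7, , ])       # identical sequences, identical maps
  pl <- trainPredictor(fixtureRecords()[1:60, ], "orthogonal",
                       arch = "linear", epochs = 2L, seed = 1L)
  expect_error(penultimateFeatures(pl, seqs), "CNN")
})

test_that("receptive fields have the closed-form widths and grow with depth", {
  widths <- vapply(1:4, function(l) receptiveField(l, 31L)$width,
                   integer(1))
  expect_identical(widths, c(5L, 9L, 18L, 26L))
  expect_true(all(diff(widths) > 0))
  rf1 <- receptiveField(1L, 31L)
  expect_equal(unname(rf1$window(3L)[1:2]), c(1, 5))
  expect_equal(unname(rf1$window(1L)[["clipped"]]), 1)   # edge clipped
})

test_that("mutations outside a kernel's receptive field never change its activation", {
  p <- fixtureOrthPredictor()
  seq0 <- randomSeqs(1, 31, seed = 9)
  bases <- c("A", "C", "G", "T")
  for (layer in c(1L, 3L)) {
    rf <- receptiveField(layer, 31L)
    f0 <- orthodesign:::.convFeatures(p, seq0, paste0("conv", layer))
    pos <- if (layer == 1L) 6L else 4L     # an interior feature position
    win <- rf$window(pos)
    outside <- setdiff(1:31, win["from"]:win["to"])
    for (q in outside[c(1, length(outside) %/% 2, length(outside))]) {
      ch <- strsplit(seq0, "")[[1]]
      ch[q] <- setdiff(bases, ch[q])[1]
      f1 <- orthodesign:::.convFeatures(p, paste(ch, collapse = ""),
                                        paste0("conv", layer))
      expect_equal(f1[1, pos, ], f0[1, pos, ], tolerance = 1e-12)
    }
    # a mutation inside the field does change some kernel's activation
    chIn <- strsplit(seq0, "")[[1]]
    mid <- (win["from"] + win["to"]) %/% 2
    chIn[mid] <- setdiff(bases, chIn[mid])[1]
    fIn <- orthodesign:::.convFeatures(p, paste(chIn, collapse = ""),
                                       paste0("conv", layer))
    expect_gt(max(abs(fIn[1, pos, ] - f0[1, pos, ])), 0)
  }
})

test_that("landscapes project one point per record and are reproducible", {
  p <- fixtureOrthPredictor()
  rec <- fixtureRecords()[1:150, ]
  ls1 <- buildLandscape(p, rec, "orthogonal", gridSize = 30L)
  ls2 <- buildLandscape(p, rec, "orthogonal", gridSize = 30L)
  expect_identical(nrow(ls1@points), 150L)
  expect_identical(ls1@points, ls2@points)
  expect_identical(ls1@grid$z, ls2@grid$z)
  expect_true(all(is.finite(ls1@grid$z)))
  expect_error(buildLandscape(p, rec, "host"), "role")
})

test_that("the host landscape has more peaks than the orthogonal one across seeds", {
  wins <- vapply(1:5, function(sd) {
    rec <- fixtureSmallRecords(sd)
    pO <- trainPredictor(rec, "orthogonal", split = "80/10/10",
                         seed = sd, epochs = 30L, patience = 30L)
    pH <- trainPredictor(rec, "host", split = "80/10/10",
                         seed = sd + 50L, epochs = 30L, patience = 30L)
    lo <- buildLandscape(pO, rec, "orthogonal", gridSize = 40L)
    lh <- buildLandscape(pH, rec, "host", gridSize = 40L)
    c(host = countLandscapePeaks(lh), orth = countLandscapePeaks(lo))
  }, numeric(2))
  expect_gt(mean(wins["host", ]), mean(wins["orth", ]))
  expect_gte(sum(wins["host", ] > wins["orth", ]), 3)
})

test_that("optimization routes project onto the landscape consistently", {
  p <- fixtureOrthPredictor()
  h <- fixtureHostPredictor()
  rec <- fixtureRecords()[1:200, ]
  ls <- buildLandscape(p, rec, "orthogonal", gridSize = 30L)
  res <- deNovoDesign(p, h, targetLevel = 1,
                      cfg = designConfig(seed = 8, maxIters = 150L),
                      wt = wildType(fixtureSystem()@orth))
  route2 <- projectTrajectory(ls, res$trajectory, nPoints = 2L)
  expect_identical(nrow(route2), 2L)
  expect_identical(route2$step[1], 0L)
  route <- projectTrajectory(ls, res$trajectory, nPoints = 8L)
  # maximisation routes end higher than they start
  expect_gt(route$z[nrow(route)], route$z[1])
  # coordinates equal independently recomputed kernel maxima
  f <- penultimateFeatures(p, route$sequence)
  expect_equal(route$kx, apply(f[, , ls@kernels[1], drop = FALSE], 1, max),
               ignore_attr = TRUE)
  expect_equal(route$ky, apply(f[, , ls@kernels[2], drop = FALSE], 1, max),
               ignore_attr = TRUE)
  tmp <- withr::local_tempfile(fileext = ".png")
  plotLandscape(ls, route = route, file = tmp)
  expect_true(file.size(tmp) > 0)
})

test_that("kernel motifs are normalised PWMs invariant to batch duplication", {
  p <- fixtureOrthPredictor()
  seqs <- fixtureRecords()$sequence[1:120]
  ms <- kernelMotifs(p, seqs, layer = 1L)
  expect_length(ms, 100L)
  nonEmpty <- Filter(function(m) !m@empty, ms)
  expect_gt(length(nonEmpty), 50)
  for (m in nonEmpty[1:10]) {
    expect_equal(rowSums(m@pwm), rep(1, 5), tolerance = 1e-9)
    expect_identical(m@width, 5L)
  }
  ms2 <- kernelMotifs(p, c(seqs, seqs), layer = 1L)
  for (k in c(1, 7, 40)) {
    if (!ms[[k]]@empty)
      expect_equal(ms2[[k]]@pwm, ms[[k]]@pwm, tolerance = 1e-12)
  }
})

test_that("a strongly conserved core is recovered in layer-1 motifs", {
  # the oracle's core centre is a planted high-effect motif; at least one
  # layer-1 kernel's PWM must concentrate information on wild-type bases
  sys <- fixtureSystem()
  p <- fixtureOrthPredictor()
  wt <- wildType(sys@orth)
  pen <- sys@orth@penalty
  centre <- which(apply(pen, 1, max) >= 0.8)       # strong positions
  # use a diverse batch: mutants plus random flanking contexts
  seqs <- c(fixtureRecords()$sequence[1:150],
            randomSeqs(50, 31, seed = 3))
  ms <- kernelMotifs(p, seqs, layer = 1L)
  planted <- encodeOneHot(substr(wt, min(centre), min(centre) + 4L))
  scores <- vapply(ms, function(m) {
    if (m@empty || m@support < 30) return(0)
    info <- pwmInformation(m)
    sum(info * rowSums(m@pwm * planted)) / max(sum(info), 1e-9)
  }, numeric(1))
  expect_gt(max(scores), 0.7)
})

test_that("motif export in MEME minimal format is well-formed", {
  p <- fixtureOrthPredictor()
  ms <- kernelMotifs(p, fixtureRecords()$sequence[1:80], layer = 1L)
  tmp <- withr::local_tempfile(fileext = ".meme")
  writeMemeMotifs(ms[1:20], tmp)
  txt <- readLines(tmp)
  expect_identical(txt[1], "MEME version 4")
  expect_true(any(grepl("^MOTIF layer1_kernel", txt)))
  probs <- grep("^[0-9.]+ [0-9.]+ [0-9.]+ [0-9.]+$", txt, value = TRUE)
  rows <- do.call(rbind, lapply(strsplit(probs, " "), as.numeric))
  expect_true(all(abs(rowSums(rows) - 1) < 1e-4))
})

test_that("well-separated motif families are recovered as pure clusters", {
  mkMotif <- function(center, k, jitter, seed) {
    withSeed <- orthodesign:::withSeed
    withSeed(seed, {
      pwm <- center + matrix(runif(20, 0, jitter), 5, 4)
      pwm <- pwm / rowSums(pwm)
      new("KernelMotif", layer = 1L, kernel = as.integer(k), pwm = pwm,
          width = 5L, support = 100L, empty = FALSE)
    })
  }
  centerA <- encodeOneHot("ACGTA") * 5 + 0.1
  centerB <- encodeOneHot("TTTCC") * 5 + 0.1
  famA <- lapply(1:8, function(i) mkMotif(centerA, i, 0.05, i))
  famB <- lapply(1:8, function(i) mkMotif(centerB, i, 0.05, 100 + i))
  rep1 <- embedAndCluster(famA, famB, seed = 5, kRange = 2:6)
  expect_gte(rep1@chosenK, 2L)
  pureTypes <- vapply(rep1@pure, function(cl)
    unique(rep1@types[rep1@membership == cl]), character(1))
  expect_setequal(unique(pureTypes), c("a", "b"))
  expect_identical(dim(rep1@embedding), c(16L, 2L))
  # identical motif sets on both sides: nothing can be pure
  rep2 <- embedAndCluster(famA, famA, seed = 5, kRange = 2:6)
  expect_length(rep2@pure, 0L)
  # determinism
  rep3 <- embedAndCluster(famA, famB, seed = 5, kRange = 2:6)
  expect_identical(rep3@membership, rep1@membership)
  expect_identical(rep3@chosenK, rep1@chosenK)
})
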