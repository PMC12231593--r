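# End-to-end pipeline: simulate -> purify -> train (host / mixed /
# orthogonal) -> design (semi-rational + de novo) -> validate ->
# landscapes -> motifs, with a JSON manifest of every metric.

#' Default run configuration
#'
#' Aggregates the defaults of all stages: the synthetic system (1252
#' records of 31 bp, triplicate), purification thresholds, the predictor
#' recipe, and the design menus (58 semi-rational designs over 8 levels,
#' 12 fixed-level designs at 1/16, 41 de novo designs over 11 levels).
#' Every stochastic stage derives its seed deterministically from the
#' global seed.
#'
#' @param seed Global seed.
#' @param ... Overrides, e.g. `system = list(n = 300)`.
#' @return Nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    system = defaultSystemConfig(seed),
    purify = list(tau1 = 10, foldTau = 2, eps = 1),
    predictor = list(arch = "cnn", split = "90/10", epochs = 300L,
                     batch = 32L, patience = 30L, lr = 5e-4, decay = 1e-6,
                     momentum = 0.9, responseScale = "log1p"),
    design = list(eta = 1, maxIters = 1000L, poolSize = 10000L,
                  maxEdit = 8L, minPairwise = 8L, hostLambda = 1,
                  tolerance = 0.1, tau1 = 10,
                  fixedLevel = 1 / 16, fixedCount = 12L),
    interpret = list(gridSize = 50L, motifLayer = 1L)
  )
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    else cfg[[nm]] <- override[[nm]]
  }
  cfg$system$seed <- cfg$seed
  cfg
}

#' Read and validate a run configuration from YAML
#'
#' Unknown top-level keys are rejected; known keys are merged over the
#' defaults and type-checked.
#'
#' @param path YAML file with a top-level `seed` and optional stage
#'   sections.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "system", "purify", "predictor", "design", "interpret")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  seed <- if (!is.null(y$seed)) y$seed else 1L
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single number")
  cfg <- do.call(defaultRunConfig,
                 c(list(seed = as.integer(seed)),
                   y[setdiff(names(y), "seed")]))
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config: ", msg)
  chk(cfg$system$n >= 10, "system$n must be >= 10")
  chk(cfg$system$L >= 8, "system$L must be >= 8")
  chk(cfg$system$replicates >= 1, "system$replicates must be >= 1")
  chk(cfg$purify$foldTau >= 1, "purify$foldTau must be >= 1")
  chk(cfg$predictor$arch %in% NN_ARCHS, "unknown predictor$arch")
  chk(cfg$design$eta > 0, "design$eta must be positive")
  chk(cfg$design$maxIters >= 1, "design$maxIters must be >= 1")
  invisible(TRUE)
}

# content hash of a configuration (stable across sessions)
.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full insulated-design pipeline
#'
#' Executes all stages and writes datasets (TSV), designs (FASTA + TSV),
#' landscape plots (PNG), motifs (MEME) and a JSON manifest into a run
#' directory named by the configuration hash. A rerun with an identical
#' configuration reuses the cached stage artifacts unless `force = TRUE`.
#'
#' @param config Configuration from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outDir Parent output directory.
#' @param force Recompute even when cached artifacts exist.
#' @param quiet Suppress stage logging.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = "runs",
                        force = FALSE, quiet = FALSE) {
  hash <- .configHash(config)
  runDir <- file.path(outDir, paste0("run-", substr(hash, 1L, 12L)))
  dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message(sprintf("[%s] %s",
    format(Sys.time(), "%H:%M:%S"), sprintf(...)))
  cache <- file.path(runDir, "state.rds")
  st <- if (file.exists(cache) && !force) readRDS(cache) else list()
  manifest <- list(configHash = hash, seed = config$seed,
                   package = as.character(utils::packageVersion("orthodesign")))

  if (is.null(st$system)) {
    log("simulate: %d records of length %d", config$system$n,
        config$system$L)
    st$system <- buildTrainingDataset(config$system)
    saveRDS(st, cache)
  }
  sys <- st$system
  writeActivityTable(systemRecords(sys), file.path(runDir, "dataset.tsv"))
  manifest$dataset <- list(n = nrow(systemRecords(sys)),
                           L = nchar(wildType(sys@orth)),
                           wt = wildType(sys@orth))

  pr <- config$predictor
  trainOne <- function(role, records) {
    trainPredictor(records, role, arch = pr$arch, split = pr$split,
                   seed = childSeed(config$seed, match(role,
                                                       PREDICTOR_ROLES)),
                   epochs = pr$epochs, batch = pr$batch,
                   patience = pr$patience, lr = pr$lr, decay = pr$decay,
                   momentum = pr$momentum,
                   responseScale = pr$responseScale)
  }

  if (is.null(st$host)) {
    log("train: host model (uninduced activities)")
    st$host <- trainOne("host", systemRecords(sys))
    saveRDS(st, cache)
  }
  if (is.null(st$purified)) {
    log("purify: tau1 = %g, foldTau = %g", config$purify$tau1,
        config$purify$foldTau)
    st$purified <- runPurification(systemRecords(sys), st$host,
                                   tau1 = config$purify$tau1,
                                   foldTau = config$purify$foldTau,
                                   eps = config$purify$eps)
    saveRDS(st, cache)
  }
  writeActivityTable(st$purified$records, file.path(runDir, "purified.tsv"))
  writeLines(purificationReportJSON(st$purified$report),
             file.path(runDir, "purification.json"))
  rep <- st$purified$report
  manifest$purification <- list(removed_step1 = rep@removedStep1,
                                removed_step2 = rep@removedStep2,
                                retained = rep@retained,
                                floored_step3 = rep@flooredStep3)

  # the orthogonal model trains on the full host-subtracted dataset; the
  # mixed model on raw induced activities of the same records
  subtracted <- step3Subtract(systemRecords(sys))$records
  if (is.null(st$orth)) {
    log("train: orthogonal model (purified activities)")
    st$orth <- trainOne("orthogonal", subtracted)
    saveRDS(st, cache)
  }
  if (is.null(st$mixed)) {
    log("train: mixed model (induced activities)")
    st$mixed <- trainOne("mixed", subtracted)
    saveRDS(st, cache)
  }
  manifest$models <- lapply(list(orthogonal = st$orth, host = st$host,
                                 mixed = st$mixed), function(p)
    list(arch = predictorArch(p), R2 = p@metrics$R2,
         pearsonR = p@metrics$pearsonR, nTest = p@metrics$nTest))

  wt <- wildType(sys@orth)
  dcfg <- designConfig(seed = childSeed(config$seed, 7L),
                       eta = config$design$eta,
                       maxIters = config$design$maxIters,
                       poolSize = config$design$poolSize,
                       maxEdit = config$design$maxEdit,
                       minPairwise = config$design$minPairwise,
                       hostLambda = config$design$hostLambda,
                       tolerance = config$design$tolerance,
                       tau1 = config$design$tau1)
  if (is.null(st$semi)) {
    log("design: semi-rational (pool %d)", dcfg$poolSize)
    st$semi <- semiRational(st$orth, st$host, wt, cfg = dcfg)
    saveRDS(st, cache)
  }
  if (is.null(st$fixed)) {
    log("design: fixed-level %g x %d", config$design$fixedLevel,
        config$design$fixedCount)
    st$fixed <- fixedLevelDiverse(st$orth, wt,
                                  level = config$design$fixedLevel,
                                  n = config$design$fixedCount,
                                  cfg = dcfg, hostPredictor = st$host)
    saveRDS(st, cache)
  }
  if (is.null(st$denovo)) {
    log("design: de novo (41 over 11 levels)")
    st$denovo <- batchDeNovo(st$orth, st$host, cfg = dcfg, wt = wt)
    saveRDS(st, cache)
  }
  if (is.null(st$denovoMixed)) {
    log("design: de novo with the mixed model (control)")
    st$denovoMixed <- batchDeNovo(st$mixed, st$host, cfg = dcfg, wt = wt)
    saveRDS(st, cache)
  }
  writeDesignSet(st$semi, file.path(runDir, "designs_semirational.fasta"),
                 file.path(runDir, "designs_semirational.tsv"))
  writeDesignSet(st$fixed, file.path(runDir, "designs_fixedlevel.fasta"),
                 file.path(runDir, "designs_fixedlevel.tsv"))
  writeDesignSet(st$denovo, file.path(runDir, "designs_denovo.fasta"),
                 file.path(runDir, "designs_denovo.tsv"))

  vSeed <- childSeed(config$seed, 8L)
  vSemi <- validateDesigns(st$semi, sys@orth, sys@host, sys@mm, vSeed)
  vDen <- validateDesigns(st$denovo, sys@orth, sys@host, sys@mm, vSeed)
  vDenM <- validateDesigns(st$denovoMixed, sys@orth, sys@host, sys@mm,
                           vSeed)
  dSemi <- designRecords(st$semi)
  dFix <- designRecords(st$fixed)
  dDen <- designRecords(st$denovo)
  manifest$designs <- list(
    semi_rational = list(
      n = nrow(dSemi), minPairwiseHamming = minPairwiseHamming(dSemi$sequence),
      validationR2 = vSemi$R2),
    fixed_level = list(
      n = nrow(dFix),
      predictedSpread = max(dFix$predicted) / min(dFix$predicted),
      minPairwiseHamming = minPairwiseHamming(dFix$sequence)),
    de_novo = list(
      n = nrow(dDen), medianHammingToWT = stats::median(dDen$hammingToWT),
      validationR2 = vDen$R2,
      validationR2_mixedModel = vDenM$R2))

  log("interpret: landscapes and motifs")
  recs <- st$purified$records
  lsOrth <- buildLandscape(st$orth, subtracted, "orthogonal",
                           gridSize = config$interpret$gridSize)
  lsHost <- buildLandscape(st$host, systemRecords(sys), "host",
                           gridSize = config$interpret$gridSize)
  lsMix <- buildLandscape(st$mixed, systemRecords(sys), "mixed",
                          gridSize = config$interpret$gridSize)
  plotLandscape(lsOrth, file = file.path(runDir, "landscape_orthogonal.png"))
  plotLandscape(lsHost, file = file.path(runDir, "landscape_host.png"))
  plotLandscape(lsMix, file = file.path(runDir, "landscape_mixed.png"))
  manifest$landscapes <- list(
    orthogonal_peaks = countLandscapePeaks(lsOrth),
    host_peaks = countLandscapePeaks(lsHost),
    mixed_peaks = countLandscapePeaks(lsMix),
    axis_kernels = lsOrth@kernels)

  mA <- kernelMotifs(st$orth, recs$sequence,
                     layer = config$interpret$motifLayer)
  mB <- kernelMotifs(st$mixed, recs$sequence,
                     layer = config$interpret$motifLayer)
  writeMemeMotifs(mA, file.path(runDir, "motifs_orthogonal.meme"))
  writeMemeMotifs(mB, file.path(runDir, "motifs_mixed.meme"))
  manifest$motifs <- list(
    layer = config$interpret$motifLayer,
    nonEmpty_orthogonal = sum(!vapply(mA, function(m) m@empty, logical(1))),
    nonEmpty_mixed = sum(!vapply(mB, function(m) m@empty, logical(1))))

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10),
             file.path(runDir, "manifest.json"))
  log("done: %s", runDir)
  invisible(c(manifest, list(runDir = runDir, state = st)))
}
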