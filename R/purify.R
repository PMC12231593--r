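# Three-step purification of host effects from paired induced/uninduced
# promoter activity measurements:
#   I.  computational removal of sequences a host-activity predictor calls
#       active in the host,
#   II. removal of promoters that do not respond to induction (activity
#       driven by the host polymerase alone),
#   III. subtraction of the uninduced (host) activity from the induced
#       activity, leaving the orthogonal-polymerase component.

#' @rdname PurificationReport-class
#' @slot removedStep1,removedStep2,retained Record counts.
#' @slot tau1 Host-activity threshold of step I.
#' @slot foldTau,eps Responsiveness ratio threshold and pseudo-count of
#'   step II.
#' @slot flooredStep3 Number of records whose purified activity was floored
#'   at zero in step III.
#' @slot flags Per-record provenance: `"retained"`, `"step1"` or `"step2"`,
#'   in input order.
#' @export
setClass("PurificationReport",
  representation(removedStep1 = "integer", removedStep2 = "integer",
                 retained = "integer", tau1 = "numeric", foldTau = "numeric",
                 eps = "numeric", flooredStep3 = "integer",
                 flags = "character"),
  validity = function(object) {
    if (object@removedStep1 + object@removedStep2 + object@retained !=
        length(object@flags))
      return("step counts must sum to the input count")
    TRUE
  })

setMethod("show", "PurificationReport", function(object) {
  n <- length(object@flags)
  cat(sprintf(
    "PurificationReport: %d records -> %d retained (step I removed %d, step II removed %d)\n",
    n, object@retained, object@removedStep1, object@removedStep2))
  cat(sprintf("  tau1 = %.3g, foldTau = %.3g, floored at 0 in step III: %d\n",
              object@tau1, object@foldTau, object@flooredStep3))
})

#' Step I: computational host-activity filter
#'
#' Removes sequences whose predicted host activity is at or above `tau1`.
#' The host predictor is a model trained on uninduced activities
#' (see [trainPredictor()] with `role = "host"`).
#'
#' @param seqs Character vector of sequences.
#' @param hostPredictor A [TrainedPredictor-class] with role `"host"`.
#' @param tau1 Host-activity threshold (same units as activities).
#' @return List with `retained` and `removed` index vectors.
#' @export
step1FilterHost <- function(seqs, hostPredictor, tau1) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  if (nchar(seqs[1L]) != hostPredictor@model$L)
    stop("sequence length does not match the host predictor")
  h <- predictActivity(hostPredictor, seqs)
  keep <- h < tau1
  list(retained = which(keep), removed = which(!keep), predictedHost = h)
}

#' Step II: remove induction-non-responsive promoters
#'
#' A promoter is kept when its induced/uninduced activity ratio (with a
#' pseudo-count) reaches `foldTau`; promoters with unchanged activity under
#' induction are host-driven and removed.
#'
#' @param records Activity `data.frame` with `induced` and `uninduced`.
#' @param foldTau Fold-change threshold (default 2).
#' @param eps Pseudo-count in activity units (default 1), stabilising the
#'   ratio at floor-level signals.
#' @return List with `retained` and `removed` index vectors.
#' @export
step2FilterNonresponsive <- function(records, foldTau = 2, eps = 1) {
  if (any(records$induced < 0, na.rm = TRUE) ||
      any(records$uninduced < 0, na.rm = TRUE))
    stop("activities must be non-negative")
  ratio <- (records$induced + eps) / (records$uninduced + eps)
  keep <- ratio >= foldTau
  list(retained = which(keep), removed = which(!keep), ratio = ratio)
}

#' Step III: subtract host activity
#'
#' Fills `purified` with `max(0, induced - uninduced)`. Negative differences
#' (possible under measurement noise) are floored at zero and counted.
#'
#' @param records Activity `data.frame`.
#' @return List with `records` (purified column filled) and `floored`
#'   (count of floored rows).
#' @export
step3Subtract <- function(records) {
  diff <- records$induced - records$uninduced
  floored <- sum(diff < 0, na.rm = TRUE)
  records$purified <- pmax(0, diff)
  list(records = records, floored = as.integer(floored))
}

#' Run the full three-step purification
#'
#' Applies steps I, II and III in order and returns the purified dataset
#' together with a [PurificationReport-class] accounting for every record.
#'
#' @param records Activity `data.frame`.
#' @param hostPredictor Host-activity [TrainedPredictor-class] for step I.
#' @param tau1 Step-I threshold.
#' @param foldTau,eps Step-II parameters.
#' @return List with `records` (retained rows, purified filled) and
#'   `report`.
#' @export
runPurification <- function(records, hostPredictor, tau1 = 10,
                            foldTau = 2, eps = 1) {
  n <- nrow(records)
  flags <- rep("retained", n)
  s1 <- step1FilterHost(records$sequence, hostPredictor, tau1)
  flags[s1$removed] <- "step1"
  kept1 <- records[s1$retained, , drop = FALSE]
  s2 <- step2FilterNonresponsive(kept1, foldTau = foldTau, eps = eps)
  flags[s1$retained[s2$removed]] <- "step2"
  kept2 <- kept1[s2$retained, , drop = FALSE]
  s3 <- step3Subtract(kept2)
  report <- new("PurificationReport",
                removedStep1 = length(s1$removed),
                removedStep2 = length(s2$removed),
                retained = nrow(kept2), tau1 = tau1, foldTau = foldTau,
                eps = eps, flooredStep3 = s3$floored, flags = flags)
  if (nrow(kept2) == 0L) {
    show(report)
    stop("purification removed every record")
  }
  list(records = s3$records, report = report)
}

#' Serialise a purification report to JSON
#'
#' @param report A [PurificationReport-class].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
purificationReportJSON <- function(report, path = NULL) {
  x <- list(input = length(report@flags),
            removed_step1 = report@removedStep1,
            removed_step2 = report@removedStep2,
            retained = report@retained,
            tau1 = report@tau1, fold_tau = report@foldTau, eps = report@eps,
            floored_step3 = report@flooredStep3)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
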