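#' @include postprocess.R
NULL

#' Voxel-level Dice score for one class
#'
#' `2 |P intersect T| / (|P| + |T|)` between the predicted and true masks
#' of `classId`; defined as 1 when both masks are empty.
#'
#' @param pred Predicted [LabelVolume-class] or integer array.
#' @param truth Ground-truth [LabelVolume-class] or integer array.
#' @param classId Class label (1 pancreas, 2 cyst).
#' @return Dice score in \[0, 1\].
#' @examples
#' diceScore(array(c(1L, 1L, 0L), c(3, 1, 1)),
#'           array(c(1L, 0L, 1L), c(3, 1, 1)), 1L)
#' @export
diceScore <- function(pred, truth, classId) {
  p <- .labVox(pred) == classId
  t <- .labVox(truth) == classId
  if (!all(dim(p) == dim(t)))
    stop("prediction and truth shapes disagree", call. = FALSE)
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0L) return(1)
  2 * sum(p & t) / (np + nt)
}

#' Classify one study's detection outcome
#'
#' Study-level detection: a case is a true positive when at least one
#' surviving predicted cyst component shares at least one voxel with the
#' ground-truth cyst mask (the minimal-overlap rule), else a false
#' negative. A control is a false positive when any predicted cyst
#' survives, else a true negative.
#'
#' @param pred Postprocessed [LabelVolume-class] or integer array.
#' @param truth Ground truth (required for cases; may be `NULL` for
#'   controls).
#' @param isCase Logical case/control status.
#' @param studyId Optional identifier carried into the outcome.
#' @param riskGroup Optional risk group carried into the outcome.
#' @param minOverlapFraction Stricter detection variants: the fraction of
#'   the true cyst mask that predicted cyst voxels must cover. The
#'   default 0 is the minimal-overlap rule (any shared voxel counts).
#' @return List of class `"StudyOutcome"`: `studyId`, `isCase`,
#'   `riskGroup`, `detected`, `outcome` (TP/FN/FP/TN), and voxel Dice for
#'   pancreas and cyst when truth is available.
#' @export
classifyStudy <- function(pred, truth = NULL, isCase, studyId = NA_character_,
                          riskGroup = if (isCase) NA_character_ else "none",
                          minOverlapFraction = 0) {
  isCase <- .assertFlag(isCase, "isCase")
  if (isCase && is.null(truth))
    stop("case studies need ground-truth labels", call. = FALSE)
  p <- .labVox(pred)
  anyCyst <- any(p == 2L)
  if (isCase) {
    t <- .labVox(truth)
    overlap <- sum(p == 2L & t == 2L)
    detected <- overlap >= 1L &&
      overlap >= minOverlapFraction * sum(t == 2L)
    outcome <- if (detected) "TP" else "FN"
  } else {
    detected <- anyCyst
    outcome <- if (anyCyst) "FP" else "TN"
  }
  out <- list(studyId = studyId, isCase = isCase, riskGroup = riskGroup,
              detected = detected, outcome = outcome,
              dicePancreas = if (!is.null(truth))
                diceScore(p, truth, 1L) else NA_real_,
              diceCyst = if (!is.null(truth))
                diceScore(p, truth, 2L) else NA_real_)
  class(out) <- "StudyOutcome"
  out
}

#' Cohort-level detection metrics
#'
#' Sensitivity `TP / (TP + FN)` over cases (overall and per cyst risk
#' group) and specificity `TN / (TN + FP)` over controls. Specificity is
#' computed once over all controls and shared across risk groups, since
#' controls carry no group. A metric whose denominator is empty is
#' reported as `NA`. Mean voxel Dice (pancreas, cyst) is averaged over
#' studies with ground truth.
#'
#' @param outcomes List of `"StudyOutcome"` objects from [classifyStudy()].
#' @return List of class `"CohortMetrics"`: `sensitivity`, `specificity`,
#'   `sensitivityByGroup` (named numeric), `dicePancreas`, `diceCyst`,
#'   and the `counts` table (TP/FN/FP/TN).
#' @examples
#' o1 <- classifyStudy(array(2L, c(1, 1, 1)), array(2L, c(1, 1, 1)), TRUE,
#'                     riskGroup = "high")
#' o2 <- classifyStudy(array(0L, c(1, 1, 1)), NULL, FALSE)
#' cohortMetrics(list(o1, o2))
#' @export
cohortMetrics <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no study outcomes", call. = FALSE)
  oc <- vapply(outcomes, function(o) o$outcome, character(1))
  grp <- vapply(outcomes, function(o) o$riskGroup %||% NA_character_,
                character(1))
  counts <- c(TP = sum(oc == "TP"), FN = sum(oc == "FN"),
              FP = sum(oc == "FP"), TN = sum(oc == "TN"))
  sens <- if (counts["TP"] + counts["FN"] > 0)
    unname(counts["TP"] / (counts["TP"] + counts["FN"])) else NA_real_
  spec <- if (counts["TN"] + counts["FP"] > 0)
    unname(counts["TN"] / (counts["TN"] + counts["FP"])) else NA_real_
  groups <- setdiff(unique(grp[oc %in% c("TP", "FN")]), NA)
  sensByGroup <- vapply(groups, function(g) {
    tp <- sum(oc == "TP" & grp == g)
    fn <- sum(oc == "FN" & grp == g)
    if (tp + fn > 0) tp / (tp + fn) else NA_real_
  }, numeric(1))
  dp <- vapply(outcomes, function(o) o$dicePancreas %||% NA_real_, numeric(1))
  dc <- vapply(outcomes, function(o) o$diceCyst %||% NA_real_, numeric(1))
  out <- list(sensitivity = sens, specificity = spec,
              sensitivityByGroup = sensByGroup,
              dicePancreas = if (any(!is.na(dp))) mean(dp, na.rm = TRUE)
                else NA_real_,
              diceCyst = if (any(!is.na(dc))) mean(dc, na.rm = TRUE)
                else NA_real_,
              counts = counts)
  class(out) <- "CohortMetrics"
  out
}

#' @export
print.CohortMetrics <- function(x, ...) {
  cat(sprintf("Cohort metrics: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  for (g in names(x$sensitivityByGroup))
    cat(sprintf("  %s-risk sensitivity %.3f\n", g, x$sensitivityByGroup[g]))
  cat(sprintf("  mean Dice: pancreas %.3f, cyst %.3f\n",
              x$dicePancreas, x$diceCyst))
  invisible(x)
}
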