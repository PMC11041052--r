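#' @include PCLseg-package.R
NULL

setClassUnion("LabelVolumeOrNULL", "NULL")

#' CTVolume: a 3D CT intensity grid
#'
#' Holds a 3D voxel array together with its voxel spacing. Intensities are
#' Hounsfield units (HU) for raw scans; [softTissueNormalize()] returns a
#' `CTVolume` whose voxels are unitless values in \[0, 1\].
#'
#' All volumes in the package live in one canonical axis convention
#' (right-anterior-superior as produced by [readVolume()]); axes are quoted
#' as (in-plane x, in-plane y, slice z) and voxel indices in user-facing
#' offsets (crop offsets, translations) are 0-based.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing Numeric length-3, mm per voxel along each axis.
#' @aliases CTVolume-class
#' @seealso [CTVolume()], [LabelVolume-class]
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite values (mm)")
    if (any(!is.finite(object@voxels)))
      return("voxel intensities must be finite")
    TRUE
  })

#' LabelVolume: a 3D segmentation grid
#'
#' Integer labels aligned with a [CTVolume-class]: 0 = background,
#' 1 = pancreas, 2 = cyst.
#'
#' @slot voxels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing Numeric length-3, mm per voxel.
#' @aliases LabelVolume-class
#' @seealso [LabelVolume()]
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array")
    if (!is.integer(object@voxels))
      return("label voxels must be stored as integers")
    if (any(is.na(object@voxels)) || any(!(object@voxels %in% 0:2)))
      return("labels must be 0 (background), 1 (pancreas) or 2 (cyst)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  })

setIs("LabelVolume", "LabelVolumeOrNULL")

#' ProbabilityVolume: per-class probability grid
#'
#' A 4D array (x, y, z, class) of per-voxel class probabilities; after the
#' TTA softmax merge, probabilities sum to 1 over classes at every voxel.
#'
#' @slot probs 4D numeric array in \[0, 1\].
#' @slot spacing Numeric length-3, mm per voxel.
#' @aliases ProbabilityVolume-class
#' @exportClass ProbabilityVolume
setClass("ProbabilityVolume",
  representation(probs = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@probs)) != 4L)
      return("probs must be a 4D (x, y, z, class) array")
    if (any(object@probs < -1e-8) || any(object@probs > 1 + 1e-8))
      return("probabilities must lie in [0, 1]")
    TRUE
  })

#' StudyRecord: one study's volumes plus metadata
#'
#' Bundles a CT with its (optional) ground-truth labels and the study-level
#' metadata the evaluation module needs: case/control status, cyst risk
#' group, and train/test split membership.
#'
#' @slot studyId Character study identifier.
#' @slot ct A [CTVolume-class].
#' @slot labels A [LabelVolume-class] or `NULL` (e.g. unlabeled test data).
#' @slot isCase Logical; `TRUE` when the study carries at least one cyst.
#' @slot riskGroup One of `"high"`, `"low"`, `"none"` (`"none"` for controls).
#' @slot split One of `"train"`, `"test"`.
#' @aliases StudyRecord-class
#' @exportClass StudyRecord
setClass("StudyRecord",
  representation(studyId = "character", ct = "CTVolume",
                 labels = "LabelVolumeOrNULL", isCase = "logical",
                 riskGroup = "character", split = "character"),
  validity = function(object) {
    if (!object@riskGroup %in% c("high", "low", "none"))
      return("riskGroup must be 'high', 'low' or 'none'")
    if (!object@split %in% c("train", "test"))
      return("split must be 'train' or 'test'")
    if (!is.null(object@labels)) {
      hasCyst <- any(object@labels@voxels == 2L)
      if (object@isCase != hasCyst)
        return("isCase must match the presence of cyst voxels in labels")
    }
    if (object@isCase == (object@riskGroup == "none"))
      return("controls must have riskGroup 'none'; cases 'high' or 'low'")
    TRUE
  })

#' AGNetModel: an attention-gate U-Net with its parameters
#'
#' @slot config Named list of architecture settings (see [agnetConfig()]).
#' @slot params Named list of weight/bias arrays.
#' @aliases AGNetModel-class
#' @seealso [agnetInit()], [agnetForward()]
#' @exportClass AGNetModel
setClass("AGNetModel",
  representation(config = "list", params = "list"),
  validity = function(object) {
    if (length(object@params) == 0L) return("params must not be empty")
    TRUE
  })
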