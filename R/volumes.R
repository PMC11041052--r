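#' @include AllGenerics.R
NULL

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of intensities (HU for raw scans).
#' @param spacing Numeric length-3 voxel spacing in mm (default 1 mm iso).
#' @return A [CTVolume-class].
#' @examples
#' ct <- CTVolume(array(0, c(8, 8, 4)), spacing = c(1.5, 1.5, 5))
#' dim(ct)
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "double"
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param voxels 3D array with values 0 (background), 1 (pancreas), 2 (cyst).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A [LabelVolume-class].
#' @export
LabelVolume <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a ProbabilityVolume
#'
#' @param probs 4D (x, y, z, class) array of probabilities.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A [ProbabilityVolume-class].
#' @export
ProbabilityVolume <- function(probs, spacing = c(1, 1, 1)) {
  new("ProbabilityVolume", probs = probs, spacing = as.numeric(spacing))
}

#' Construct a StudyRecord
#'
#' @param studyId Character identifier.
#' @param ct A [CTVolume-class].
#' @param labels A [LabelVolume-class] or `NULL`.
#' @param isCase Logical case/control flag.
#' @param riskGroup `"high"`, `"low"` or `"none"`.
#' @param split `"train"` or `"test"`.
#' @return A [StudyRecord-class].
#' @export
StudyRecord <- function(studyId, ct, labels = NULL, isCase = FALSE,
                        riskGroup = "none", split = "train") {
  new("StudyRecord", studyId = as.character(studyId), ct = ct,
      labels = labels, isCase = isCase, riskGroup = riskGroup, split = split)
}

#' @rdname voxelData
#' @export
setMethod("voxelData", "CTVolume", function(x) x@voxels)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@voxels)
#' @rdname voxelData
#' @export
setMethod("voxelData", "ProbabilityVolume", function(x) x@probs)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ProbabilityVolume", function(x) x@spacing)

#' @describeIn CTVolume-class dimensions of the voxel grid
#' @param x a volume object
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))
#' @describeIn LabelVolume-class dimensions of the voxel grid
#' @param x a volume object
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %dx%dx%d, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  tab <- tabulate(object@voxels + 1L, nbins = 3L)
  cat(sprintf(
    "LabelVolume %dx%dx%d: %d background, %d pancreas, %d cyst voxels\n",
    d[1], d[2], d[3], tab[1], tab[2], tab[3]))
})

setMethod("show", "StudyRecord", function(object) {
  cat(sprintf("StudyRecord '%s': %s, risk group %s, split %s\n",
              object@studyId, if (object@isCase) "case" else "control",
              object@riskGroup, object@split))
})

#' Study identifier accessor
#' @param x A [StudyRecord-class].
#' @return Character study id.
#' @export
studyId <- function(x) x@studyId

#' Case/control flag accessor
#' @param x A [StudyRecord-class].
#' @return Logical.
#' @export
isCase <- function(x) x@isCase

#' Risk-group accessor
#' @param x A [StudyRecord-class].
#' @return `"high"`, `"low"` or `"none"`.
#' @export
riskGroup <- function(x) x@riskGroup
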