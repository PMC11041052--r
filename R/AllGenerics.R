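#' @include AllClasses.R
NULL

#' Extract the voxel array from a volume object
#' @param x A [CTVolume-class], [LabelVolume-class] or
#'   [ProbabilityVolume-class].
#' @return The underlying array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Extract the voxel spacing (mm) from a volume object
#' @param x A volume object.
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Number of trainable parameters of a model
#' @param object An [AGNetModel-class].
#' @return Integer parameter count.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))
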