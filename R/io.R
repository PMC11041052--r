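#' @include volumes.R
NULL

#' Read a CT or label volume from NIfTI
#'
#' Reads a NIfTI-1 file and reorients it to the package-wide canonical
#' right-anterior-superior (RAS) axis convention, so that "in-plane"
#' operations (cropping, rotations, translations) always act on the first
#' two axes. Voxel spacing is taken from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label Logical; read as a [LabelVolume-class] (integer labels)
#'   rather than a [CTVolume-class].
#' @return A [CTVolume-class] or [LabelVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(CTVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4))), f)
#' readVolume(f)
#' @export
readVolume <- function(path, label = FALSE) {
  # RNifti duplicates read failures as warning + error; keep the error
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), " dimensions",
         call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  spacing <- RNifti::pixdim(img)[1:3]
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  if (label) LabelVolume(round(vox), spacing = spacing)
  else CTVolume(vox, spacing = spacing)
}

#' Write a volume to NIfTI
#'
#' Writes voxels and spacing to a NIfTI-1 file in the canonical RAS
#' orientation; label volumes are stored with an integer datatype so labels
#' round-trip exactly.
#'
#' @param vol A [CTVolume-class] or [LabelVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  isLabel <- is(vol, "LabelVolume")
  sp <- voxelSpacing(vol)
  img <- RNifti::asNifti(voxelData(vol))
  # RAS-aligned scaling xform so orientation metadata round-trips
  RNifti::sform(img) <- structure(rbind(cbind(diag(sp), c(0, 0, 0)),
                                        c(0, 0, 0, 1)), code = 2L)
  RNifti::pixdim(img) <- sp
  tryCatch(
    RNifti::writeNifti(img, path,
                       datatype = if (isLabel) "int16" else "double"),
    error = function(e) stop("failed to write NIfTI file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}
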