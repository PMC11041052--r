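#' @include volumes.R
NULL

#' Preprocessing configuration
#'
#' The two preprocessing steps applied to every CT before segmentation:
#' soft-tissue intensity windowing (clip to `windowCenter +/-
#' windowHalfwidth` HU, then rescale linearly to \[0, 1\]) and central
#' in-plane cropping to `cropSize` x `cropSize` voxels. Defaults match the
#' clinical pipeline: a 50 +/- 100 HU soft-tissue window (the pancreas and
#' most cystic lesions sit near 50 HU) and a 240-voxel central crop of a
#' 512 x 512 slice, keeping the centre of the abdomen where the pancreas
#' lies.
#'
#' @param windowCenter Window centre in HU.
#' @param windowHalfwidth Half-width of the window in HU (> 0).
#' @param cropSize In-plane crop size in voxels (> 0).
#' @return Named list of class `"PreprocessConfig"`.
#' @examples
#' preprocessConfig()
#' @export
preprocessConfig <- function(windowCenter = 50, windowHalfwidth = 100,
                             cropSize = 240L) {
  if (windowHalfwidth <= 0) stop("windowHalfwidth must be > 0", call. = FALSE)
  cropSize <- .assertCount(cropSize, "cropSize", min = 1L)
  structure(list(windowCenter = windowCenter,
                 windowHalfwidth = windowHalfwidth,
                 cropSize = cropSize),
            class = "PreprocessConfig")
}

#' Soft-tissue intensity normalization
#'
#' Clips HU values to `windowCenter +/- windowHalfwidth` and maps the
#' window linearly onto \[0, 1\] (so with defaults -50 HU -> 0, 50 HU ->
#' 0.5, 150 HU -> 1). The map is monotone non-decreasing in HU.
#'
#' @param ct A [CTVolume-class] (HU) or 3D array.
#' @param cfg A [preprocessConfig()].
#' @return Object of the same kind as `ct` with unitless voxels in \[0, 1\].
#' @examples
#' softTissueNormalize(array(c(-200, 50, 400), c(3, 1, 1)))
#' @export
softTissueNormalize <- function(ct, cfg = preprocessConfig()) {
  vox <- if (is(ct, "CTVolume")) voxelData(ct) else ct
  if (any(!is.finite(vox)))
    stop("CT contains non-finite voxel values", call. = FALSE)
  lo <- cfg$windowCenter - cfg$windowHalfwidth
  hi <- cfg$windowCenter + cfg$windowHalfwidth
  out <- (pmin(pmax(vox, lo), hi) - lo) / (hi - lo)
  dim(out) <- dim(vox)
  if (is(ct, "CTVolume")) CTVolume(out, voxelSpacing(ct)) else out
}

# 0-based in-plane offset of the central crop window; an odd remainder
# leaves the extra voxel on the high side.
.cropOffset <- function(shape, cropSize) {
  c(floor((shape[1] - cropSize) / 2), floor((shape[2] - cropSize) / 2))
}

#' Central in-plane crop
#'
#' Crops the first two (in-plane) axes to `cropSize` x `cropSize` voxels
#' around the volume centre; the slice axis is untouched. When the
#' remainder is odd the extra voxel is kept on the high side. Inputs
#' smaller than `cropSize` in-plane are an error; no padding is performed.
#'
#' @param vol A [CTVolume-class], [LabelVolume-class] or 3D array.
#' @param cfg A [preprocessConfig()].
#' @return Cropped object of the same kind as `vol`.
#' @examples
#' dim(centralCrop(array(0, c(512, 512, 3)), preprocessConfig()))
#' @export
centralCrop <- function(vol, cfg = preprocessConfig()) {
  vox <- if (isS4(vol)) voxelData(vol) else vol
  d <- dim(vox)
  cs <- cfg$cropSize
  if (d[1] < cs || d[2] < cs)
    stop("in-plane size ", d[1], "x", d[2], " smaller than crop size ", cs,
         "; refusing to pad", call. = FALSE)
  off <- .cropOffset(d, cs)
  out <- vox[off[1] + seq_len(cs), off[2] + seq_len(cs), , drop = FALSE]
  if (is(vol, "CTVolume")) CTVolume(out, voxelSpacing(vol))
  else if (is(vol, "LabelVolume")) LabelVolume(out, voxelSpacing(vol))
  else out
}

#' Place a cropped prediction back into the original grid
#'
#' Inverse of [centralCrop()] for predictions: the cropped label volume is
#' written at the crop offset of `originalShape`; everything outside the
#' crop window is background (0). Inside the crop window,
#' `uncrop(centralCrop(x))` restores `x` exactly.
#'
#' @param pred Cropped [LabelVolume-class] or 3D array.
#' @param originalShape Integer length-3 shape of the uncropped volume.
#' @param cfg The [preprocessConfig()] used for cropping.
#' @return Full-size object of the same kind as `pred`.
#' @export
uncrop <- function(pred, originalShape, cfg = preprocessConfig()) {
  vox <- if (isS4(pred)) voxelData(pred) else pred
  d <- dim(vox)
  cs <- cfg$cropSize
  if (d[1] != cs || d[2] != cs || d[3] != originalShape[3])
    stop("cropped prediction shape ", paste(d, collapse = "x"),
         " inconsistent with crop size ", cs, " and original shape ",
         paste(originalShape, collapse = "x"), call. = FALSE)
  off <- .cropOffset(originalShape, cs)
  out <- array(if (is.integer(vox)) 0L else 0, originalShape)
  out[off[1] + seq_len(cs), off[2] + seq_len(cs), ] <- vox
  if (is(pred, "LabelVolume")) LabelVolume(out, pred@spacing)
  else if (is(pred, "CTVolume")) CTVolume(out, pred@spacing)
  else out
}
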