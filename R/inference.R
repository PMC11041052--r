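#' @include agnet.R
NULL

#' Construct a test-time-augmentation transform
#'
#' An invertible in-plane (axial) geometric transform: a rotation about
#' the slice centre (degrees, bilinear interpolation) or an integer
#' translation along one in-plane axis (voxels). Its inverse is the same
#' kind with negated magnitude; `inverse o forward` restores a volume up
#' to interpolation tolerance (exactly, for translations).
#'
#' @param kind `"rotation"` or `"translation"`.
#' @param magnitude Degrees (rotation) or voxels (translation; integer).
#' @param axis In-plane translation axis, 1 or 2 (ignored for rotations).
#' @return Object of class `"TTATransform"`.
#' @export
ttaTransform <- function(kind = c("rotation", "translation"), magnitude,
                         axis = 1L) {
  kind <- match.arg(kind)
  if (kind == "translation" && magnitude != round(magnitude))
    stop("translations are whole-voxel shifts", call. = FALSE)
  if (!axis %in% 1:2) stop("axis must be in-plane (1 or 2)", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, axis = as.integer(axis)),
            class = "TTATransform")
}

#' Invert a TTA transform
#' @param t A [ttaTransform()].
#' @return The inverse transform (same kind, negated magnitude).
#' @export
invertTransform <- function(t) {
  stopifnot(inherits(t, "TTATransform"))
  ttaTransform(t$kind, -t$magnitude, t$axis)
}

#' The default test-time-augmentation set
#'
#' Exactly four in-plane transforms: a positive rotation of 7 degrees, a
#' negative rotation of 11 degrees, and two positive translations of 5 and
#' 10 voxels. Rotations in both directions cover abdomens tilted either
#' way; flips are deliberately absent (anatomy is chiral) and larger sets
#' were rejected for latency.
#'
#' @return List of 4 [ttaTransform()] objects.
#' @examples
#' length(defaultTTA())
#' @export
defaultTTA <- function() {
  list(ttaTransform("rotation", 7),
       ttaTransform("rotation", -11),
       ttaTransform("translation", 5),
       ttaTransform("translation", 10))
}

# Shift `arr` (3D or 4D) by m voxels along an in-plane axis; vacated
# voxels get `pad` and are flagged invalid.
.translateArr <- function(arr, m, axis, pad) {
  d <- dim(arr)
  out <- array(pad, d)
  valid <- matrix(0, d[1], d[2])
  n <- d[axis]
  if (abs(m) < n) {
    dst <- if (m >= 0) (m + 1):n else 1:(n + m)
    src <- dst - m
    if (axis == 1L) {
      if (length(d) == 3L) out[dst, , ] <- arr[src, , ]
      else out[dst, , , ] <- arr[src, , , ]
      valid[dst, ] <- 1
    } else {
      if (length(d) == 3L) out[, dst, ] <- arr[, src, ]
      else out[, dst, , ] <- arr[, src, , ]
      valid[, dst] <- 1
    }
  }
  list(data = out, valid = valid)
}

#' Apply a TTA transform to a volume
#'
#' Works on 3D intensity volumes and on 4D per-class score volumes (each
#' channel transformed identically). Returns the transformed data plus an
#' in-plane validity map that flags positions whose value originated
#' inside the field of view; out-of-field positions carry `pad`.
#'
#' @param arr 3D or 4D array.
#' @param t A [ttaTransform()].
#' @param pad Fill value for out-of-field voxels (window minimum, 0, for
#'   normalized intensities).
#' @return List with `data` (same shape as `arr`) and `valid` (in-plane
#'   matrix in \[0, 1\]).
#' @export
applyTransform <- function(arr, t, pad = 0) {
  stopifnot(inherits(t, "TTATransform"))
  if (t$kind == "rotation")
    cpp_rotate_inplane(arr, dim(arr), t$magnitude, pad)
  else
    .translateArr(arr, as.integer(t$magnitude), t$axis, pad)
}

#' Sliding-window whole-volume inference
#'
#' Tiles the volume with patches of `patchSize`, runs the network on each
#' patch, and averages logits voxel-wise over overlapping patches so that
#' every voxel is covered at least once. The final tile along each axis is
#' shifted inward to end at the volume boundary.
#'
#' @param model An [AGNetModel-class].
#' @param vol 3D array of normalized intensities (at least patch-sized).
#' @param patchSize Integer length-3 patch shape.
#' @param stride Integer length-3 tile stride; defaults to half the patch.
#'   Strides larger than the patch would leave coverage gaps and are an
#'   error.
#' @return 4D (x, y, z, class) logits array.
#' @export
slidingWindowInfer <- function(model, vol, patchSize,
                               stride = NULL) {
  stopifnot(is(model, "AGNetModel"))
  d <- dim(vol)
  patchSize <- as.integer(rep(patchSize, length.out = 3L))
  if (is.null(stride)) stride <- pmax(patchSize %/% 2L, 1L)
  stride <- as.integer(rep(stride, length.out = 3L))
  if (any(d < patchSize))
    stop("volume ", paste(d, collapse = "x"), " smaller than patch ",
         paste(patchSize, collapse = "x"), call. = FALSE)
  if (any(stride > patchSize))
    stop("stride exceeds patch size; tiles would leave coverage gaps",
         call. = FALSE)
  offs <- lapply(1:3, function(a) {
    o <- seq.int(0L, d[a] - patchSize[a], by = stride[a])
    unique(c(o, d[a] - patchSize[a]))
  })
  nc <- model@config$nClasses
  acc <- array(0, c(d, nc))
  cnt <- array(0, d)
  for (oz in offs[[3]]) for (oy in offs[[2]]) for (ox in offs[[1]]) {
    ix <- ox + seq_len(patchSize[1])
    iy <- oy + seq_len(patchSize[2])
    iz <- oz + seq_len(patchSize[3])
    lg <- agnetForward(model, vol[ix, iy, iz, drop = FALSE])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + lg
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  acc / as.vector(cnt)
}

.softmax4 <- function(logits) {
  d <- dim(logits)
  pm <- .softmaxMat(matrix(logits, prod(d[1:3]), d[4]))
  array(pm, d)
}

#' Inference with test-time augmentation
#'
#' Runs sliding-window inference on the untransformed volume and on each
#' transformed copy, maps every per-class output back through the inverse
#' transform, and merges the passes by averaging per-class scores
#' voxel-wise; a softmax then yields the final probabilities and the
#' per-voxel argmax the label map. Scores are averaged pre-softmax (the
#' merge precedes the softmax), and voxels that re-enter from out-of-field
#' padding under a transform are excluded from that pass's average via the
#' transform's validity map — the untransformed pass guarantees every
#' voxel at least one contribution. Averaging makes the merge invariant
#' to the order of the transforms.
#'
#' @param model An [AGNetModel-class].
#' @param vol 3D array of normalized intensities.
#' @param transforms List of [ttaTransform()]s (default [defaultTTA()]);
#'   an empty list reduces to plain inference.
#' @param patchSize Integer length-3 patch shape.
#' @param stride Tile stride, as in [slidingWindowInfer()].
#' @param pad Out-of-field fill value for intensities.
#' @return List with `probs` (4D per-class probabilities summing to 1 per
#'   voxel), `labels` (3D integer argmax map) and `logits` (merged 4D
#'   scores).
#' @export
ttaPredict <- function(model, vol, transforms = defaultTTA(), patchSize,
                       stride = NULL, pad = 0) {
  d <- dim(vol)
  nc <- model@config$nClasses
  acc <- array(0, c(d, nc))
  wsum <- array(0, d)
  addPass <- function(logits, w) {
    acc <<- acc + logits * as.vector(w)
    wsum <<- wsum + w
  }
  addPass(slidingWindowInfer(model, vol, patchSize, stride), array(1, d))
  for (t in transforms) {
    stopifnot(inherits(t, "TTATransform"))
    fw <- applyTransform(vol, t, pad = pad)
    lg <- slidingWindowInfer(model, fw$data, patchSize, stride)
    inv <- invertTransform(t)
    back <- applyTransform(lg, inv, pad = 0)
    fwValid <- array(rep(fw$valid, d[3]), d)
    vback <- applyTransform(fwValid, inv, pad = 0)
    w <- (vback$data > 0.999) * array(rep(vback$valid, d[3]), d)
    lgBack <- back$data
    lgBack[!is.finite(lgBack)] <- 0
    addPass(lgBack, w)
  }
  merged <- acc / as.vector(wsum)
  probs <- .softmax4(merged)
  labels <- array(max.col(matrix(probs, prod(d), nc),
                          ties.method = "first") - 1L, d)
  list(probs = probs, labels = labels, logits = merged)
}
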