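#' @include volumes.R
NULL

#' Postprocessing configuration
#'
#' The three false-positive filters applied, in order, to every predicted
#' segmentation: (1) predictions outside an eroded abdomen mask are
#' removed (wrong detections at the body edge), (2) cyst components not in
#' touch with predicted pancreas are removed, and (3) cyst components
#' smaller than `minCystVoxels` are removed — a predicted cyst needs a
#' minimum of 10 voxels to count.
#'
#' @param abdomenHuThreshold HU threshold separating body from air.
#' @param erosionRadius Abdomen-mask erosion radius in voxels (ball
#'   structuring element; 0 disables erosion).
#' @param contactConnectivity Neighbourhood for the pancreas-contact test
#'   (6, 18 or 26).
#' @param minCystVoxels Minimum surviving cyst component size (inclusive:
#'   a component with exactly this many voxels survives).
#' @param componentConnectivity Neighbourhood used to define cyst
#'   connected components.
#' @return Named list of class `"PostprocessConfig"`.
#' @export
postprocessConfig <- function(abdomenHuThreshold = -500, erosionRadius = 3,
                              contactConnectivity = 26L,
                              minCystVoxels = 10L,
                              componentConnectivity = 26L) {
  if (!contactConnectivity %in% c(6L, 18L, 26L) ||
      !componentConnectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  if (erosionRadius < 0) stop("erosionRadius must be >= 0", call. = FALSE)
  structure(list(abdomenHuThreshold = abdomenHuThreshold,
                 erosionRadius = erosionRadius,
                 contactConnectivity = as.integer(contactConnectivity),
                 minCystVoxels = .assertCount(minCystVoxels, "minCystVoxels",
                                              min = 1L),
                 componentConnectivity = as.integer(componentConnectivity)),
            class = "PostprocessConfig")
}

.labVox <- function(x) if (is(x, "LabelVolume")) voxelData(x) else x
.intArr <- function(x) {
  storage.mode(x) <- "integer"
  x
}

#' Eroded abdomen mask from a CT volume
#'
#' Thresholds the (pre-normalization, HU) volume at `abdomenHuThreshold`,
#' keeps the largest connected component (the body), fills internal
#' cavities (bowel gas, lungs) and erodes by a ball of `erosionRadius`
#' voxels so the body edge is excluded.
#'
#' @param ct A [CTVolume-class] or 3D HU array.
#' @param cfg A [postprocessConfig()].
#' @return 3D integer 0/1 array.
#' @export
abdomenMask <- function(ct, cfg = postprocessConfig()) {
  vox <- if (is(ct, "CTVolume")) voxelData(ct) else ct
  d <- dim(vox)
  thr <- .intArr(array(as.integer(vox >= cfg$abdomenHuThreshold), d))
  if (!any(thr == 1L))
    stop("no voxel above the abdomen threshold; degenerate input",
         call. = FALSE)
  lab <- cpp_label_components(thr, d, 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- .intArr(array(as.integer(lab == keep), d))
  mask <- cpp_fill_holes(mask, d)
  if (cfg$erosionRadius > 0) mask <- cpp_erode_ball(mask, d, cfg$erosionRadius)
  mask
}

.emptyReport <- function() {
  data.frame(component_id = integer(0), n_voxels = integer(0),
             touches_pancreas = logical(0), inside_abdomen = logical(0),
             removed_by = character(0), stringsAsFactors = FALSE)
}

#' Remove predictions outside the abdomen mask
#'
#' Sets predicted pancreas and cyst voxels outside the (eroded) abdomen
#' mask to background. Components partially outside only lose their
#' outside voxels.
#'
#' @param pred A [LabelVolume-class] or 3D integer array.
#' @param mask 0/1 mask from [abdomenMask()].
#' @param cfg A [postprocessConfig()].
#' @return List with `pred` (filtered, same kind as input) and `report`
#'   (one row per original cyst component; `removed_by == "abdomen"` for
#'   components entirely outside the mask).
#' @export
filterOutsideAbdomen <- function(pred, mask, cfg = postprocessConfig()) {
  vox <- .labVox(pred)
  if (!all(dim(vox) == dim(mask)))
    stop("prediction and mask shapes disagree", call. = FALSE)
  d <- dim(vox)
  comp <- cpp_label_components(.intArr(array(as.integer(vox == 2L), d)), d,
                               cfg$componentConnectivity)
  out <- vox
  out[mask == 0L] <- 0L
  rep <- .componentReport(comp, out, stage = "abdomen", mask = mask)
  list(pred = .rewrap(pred, out), report = rep)
}

#' Remove cysts not in touch with the pancreas
#'
#' Every predicted cyst connected component with no voxel adjacent
#' (under `contactConnectivity`) to a predicted pancreas voxel is set to
#' background. Contact is evaluated against the prediction itself, not
#' ground truth, so the filter runs on unlabeled studies; if no pancreas
#' is predicted at all, every cyst is removed (and reported).
#'
#' @inheritParams filterOutsideAbdomen
#' @return List with `pred` and `report` (components removed here carry
#'   `removed_by == "contact"`).
#' @export
filterNoncontactCysts <- function(pred, cfg = postprocessConfig()) {
  vox <- .labVox(pred)
  d <- dim(vox)
  comp <- cpp_label_components(.intArr(array(as.integer(vox == 2L), d)), d,
                               cfg$componentConnectivity)
  k <- max(comp)
  out <- vox
  if (k > 0L) {
    touch <- cpp_touching_labels(comp, .intArr(array(as.integer(vox == 1L), d)),
                                 d, cfg$contactConnectivity, k)
    drop <- which(!touch)
    out[comp %in% drop] <- 0L
  }
  rep <- .componentReport(comp, out, stage = "contact",
                          pancreas = array(vox == 1L, d),
                          cfg = cfg)
  list(pred = .rewrap(pred, out), report = rep)
}

#' Remove undersized cyst components
#'
#' Cyst components with fewer than `minCystVoxels` voxels are set to
#' background; components with at least that many survive (the minimum is
#' inclusive).
#'
#' @inheritParams filterOutsideAbdomen
#' @return List with `pred` and `report` (`removed_by == "size"`).
#' @export
filterSmallComponents <- function(pred, cfg = postprocessConfig()) {
  vox <- .labVox(pred)
  d <- dim(vox)
  comp <- cpp_label_components(.intArr(array(as.integer(vox == 2L), d)), d,
                               cfg$componentConnectivity)
  k <- max(comp)
  out <- vox
  if (k > 0L) {
    sizes <- tabulate(comp[comp > 0L], nbins = k)
    drop <- which(sizes < cfg$minCystVoxels)
    out[comp %in% drop] <- 0L
  }
  rep <- .componentReport(comp, out, stage = "size")
  list(pred = .rewrap(pred, out), report = rep)
}

.rewrap <- function(orig, vox) {
  if (is(orig, "LabelVolume")) LabelVolume(vox, orig@spacing) else .intArr(vox)
}

# Per-component bookkeeping for a single stage: which original components
# lost all voxels at this stage.
.componentReport <- function(comp, out, stage, mask = NULL, pancreas = NULL,
                             cfg = NULL) {
  k <- max(comp)
  if (k == 0L) return(.emptyReport())
  sizes <- tabulate(comp[comp > 0L], nbins = k)
  left <- tabulate(comp[out == 2L], nbins = k)
  inside <- if (!is.null(mask))
    tabulate(comp[comp > 0L & mask == 1L], nbins = k) > 0L
  else rep(NA, k)
  touches <- if (!is.null(pancreas) && !is.null(cfg)) {
    as.logical(cpp_touching_labels(comp,
                                   .intArr(array(as.integer(pancreas),
                                                 dim(comp))),
                                   dim(comp), cfg$contactConnectivity, k))
  } else rep(NA, k)
  data.frame(component_id = seq_len(k), n_voxels = sizes,
             touches_pancreas = touches, inside_abdomen = inside,
             removed_by = ifelse(left == 0L, stage, "none"),
             stringsAsFactors = FALSE)
}

#' Full postprocessing pipeline
#'
#' Applies the three filters in their clinical order — abdomen mask, then
#' pancreas contact, then minimum size — and accounts for every original
#' cyst component exactly once: `removed_by` names the first stage after
#' which a component had no voxels left (`"none"` for survivors). Filters
#' only ever remove voxels, so the surviving prediction is a voxel-wise
#' subset of the input and the pipeline is idempotent.
#'
#' @param pred Predicted [LabelVolume-class] or 3D integer array, aligned
#'   with `ct`.
#' @param ct The corresponding [CTVolume-class] in original HU (before
#'   normalization), used to build the abdomen mask.
#' @param cfg A [postprocessConfig()].
#' @return List with `pred` (filtered prediction, same kind as the input)
#'   and `report` (data.frame: `component_id`, `n_voxels`,
#'   `touches_pancreas`, `inside_abdomen`, `removed_by`).
#' @export
postprocessPipeline <- function(pred, ct, cfg = postprocessConfig()) {
  vox <- .labVox(pred)
  ctVox <- if (is(ct, "CTVolume")) voxelData(ct) else ct
  if (!all(dim(vox) == dim(ctVox)))
    stop("prediction and CT shapes disagree", call. = FALSE)
  d <- dim(vox)
  comp0 <- cpp_label_components(.intArr(array(as.integer(vox == 2L), d)), d,
                                cfg$componentConnectivity)
  k <- max(comp0)
  mask <- abdomenMask(ctVox, cfg)

  cur <- vox
  cur[mask == 0L] <- 0L
  afterAbdomen <- tabulate(comp0[cur == 2L], nbins = k)

  comp1 <- cpp_label_components(.intArr(array(as.integer(cur == 2L), d)), d,
                                cfg$componentConnectivity)
  k1 <- max(comp1)
  if (k1 > 0L) {
    touch <- cpp_touching_labels(comp1,
                                 .intArr(array(as.integer(cur == 1L), d)), d,
                                 cfg$contactConnectivity, k1)
    cur[array(comp1 %in% which(!touch), d)] <- 0L
  }
  afterContact <- tabulate(comp0[cur == 2L], nbins = k)

  comp2 <- cpp_label_components(.intArr(array(as.integer(cur == 2L), d)), d,
                                cfg$componentConnectivity)
  k2 <- max(comp2)
  if (k2 > 0L) {
    sizes2 <- tabulate(comp2[comp2 > 0L], nbins = k2)
    cur[array(comp2 %in% which(sizes2 < cfg$minCystVoxels), d)] <- 0L
  }
  afterSize <- tabulate(comp0[cur == 2L], nbins = k)

  report <- if (k == 0L) .emptyReport() else {
    sizes <- tabulate(comp0[comp0 > 0L], nbins = k)
    inside <- tabulate(comp0[comp0 > 0L & mask == 1L], nbins = k) > 0L
    touches <- as.logical(
      cpp_touching_labels(comp0, .intArr(array(as.integer(vox == 1L), d)), d,
                          cfg$contactConnectivity, k))
    removedBy <- rep("none", k)
    removedBy[afterSize == 0L] <- "size"
    removedBy[afterContact == 0L] <- "contact"
    removedBy[afterAbdomen == 0L] <- "abdomen"
    data.frame(component_id = seq_len(k), n_voxels = sizes,
               touches_pancreas = touches, inside_abdomen = inside,
               removed_by = removedBy, stringsAsFactors = FALSE)
  }
  list(pred = .rewrap(pred, cur), report = report)
}
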