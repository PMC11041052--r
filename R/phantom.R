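#' @include volumes.R
NULL

#' Default tissue intensity models for the abdominal phantom
#'
#' Mean Hounsfield values and per-tissue Gaussian noise scales for the
#' synthetic abdomen: air around the body, a subcutaneous fat ring, soft
#' tissue filling the abdomen, a vertebral bone cylinder, the pancreas, and
#' near-water cysts. Means are ordered air < fat < cyst < soft tissue <
#' bone, mirroring the CT scale (air -1000 HU, water 0 HU, soft tissue
#' 30-60 HU, pancreas about 50 HU).
#'
#' @return `data.frame` with columns `name`, `mean_hu`, `sd_hu`.
#' @examples
#' tissueModel()
#' @export
tissueModel <- function() {
  tm <- data.frame(
    name    = c("air", "fat", "cyst", "soft", "pancreas", "bone"),
    mean_hu = c(-1000, -100, 5, 30, 55, 400),
    sd_hu   = c(5, 10, 8, 10, 10, 30),
    stringsAsFactors = FALSE)
  .validateTissues(tm)
  tm
}

.validateTissues <- function(tm) {
  need <- c("air", "fat", "cyst", "soft", "pancreas", "bone")
  if (!all(need %in% tm$name))
    stop("tissue model must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- function(n) tm$mean_hu[tm$name == n]
  if (!(m("air") < m("fat") && m("fat") < m("cyst") &&
        m("cyst") < m("soft") && m("soft") < m("bone")))
    stop("tissue means must be ordered air < fat < cyst < soft < bone",
         call. = FALSE)
  if (any(tm$sd_hu < 0)) stop("tissue sd_hu must be >= 0", call. = FALSE)
  invisible(tm)
}

#' Specification of one synthetic abdominal phantom
#'
#' Describes the grid, the tissues, and the cysts to synthesize. The default
#' 64 x 64 x 32 grid at 1.5 x 1.5 x 5 mm spacing is the package's desk-scale
#' working size; all geometry scales with the grid.
#'
#' @param gridShape Integer length-3 voxel grid (each axis >= 32).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param nCysts Number of cysts (>= 0).
#' @param cystRadiusRange Numeric length-2 cyst radius range in voxels.
#' @param cystAttached Logical; cysts must touch the pancreas (the clinical
#'   situation). `FALSE` plants detached cysts, exercising the
#'   pancreas-contact filter's removal path.
#' @param riskGroup Optional character vector (length `nCysts`) of
#'   `"high"`/`"low"` per cyst; `NULL` samples groups at random. High-risk
#'   cysts draw radii from the upper half of `cystRadiusRange`, low-risk
#'   from the lower half.
#' @param noiseSd Global additive Gaussian noise in HU, on top of each
#'   tissue's own `sd_hu`.
#' @param tissues Tissue table as from [tissueModel()].
#' @param seed Integer seed; identical (spec, seed) pairs yield identical
#'   phantoms.
#' @return Named list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 32L),
                        spacing = c(1.5, 1.5, 5),
                        nCysts = 1L,
                        cystRadiusRange = c(3, 5),
                        cystAttached = TRUE,
                        riskGroup = NULL,
                        noiseSd = 10,
                        tissues = tissueModel(),
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 32L))
    stop("gridShape must have 3 axes, each >= 32 voxels", call. = FALSE)
  nCysts <- .assertCount(nCysts, "nCysts")
  if (length(cystRadiusRange) != 2L || any(cystRadiusRange <= 0) ||
      cystRadiusRange[1] > cystRadiusRange[2])
    stop("cystRadiusRange must be increasing and positive", call. = FALSE)
  if (cystRadiusRange[2] > min(gridShape) / 4)
    stop("cyst radii too large for the grid", call. = FALSE)
  if (!is.null(riskGroup)) {
    if (length(riskGroup) != nCysts || !all(riskGroup %in% c("high", "low")))
      stop("riskGroup must give 'high'/'low' for each cyst", call. = FALSE)
  }
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  .validateTissues(tissues)
  structure(list(gridShape = gridShape, spacing = as.numeric(spacing),
                 nCysts = nCysts, cystRadiusRange = as.numeric(cystRadiusRange),
                 cystAttached = .assertFlag(cystAttached, "cystAttached"),
                 riskGroup = riskGroup, noiseSd = noiseSd, tissues = tissues,
                 seed = .assertCount(seed, "seed")),
            class = "PhantomSpec")
}

# Geometry masks for one phantom. The abdomen cross-section is a
# superellipse (exponent 2.5); the pancreas an elongated ellipsoid slightly
# anterior of centre; a bone cylinder sits posteriorly. Shapes are
# deliberately simple: the pipeline's filters depend on intensity,
# adjacency and size, not anatomical realism.
.phantomGeometry <- function(gs) {
  X <- gs[1]; Y <- gs[2]; Z <- gs[3]
  cx <- (X + 1) / 2; cy <- (Y + 1) / 2; cz <- (Z + 1) / 2
  xi <- ((1:X) - cx) / X
  yi <- ((1:Y) - cy) / Y
  zi <- ((1:Z) - cz) / Z
  sxy <- outer(abs(xi / 0.44)^2.5, abs(yi / 0.38)^2.5, `+`)
  s <- array(rep(sxy, Z), c(X, Y, Z))
  body <- s <= 1            # abdomen incl. fat ring
  inner <- s <= 0.72        # soft-tissue interior
  bone2d <- outer((xi * X)^2, ((yi + 0.26) * Y)^2, `+`) <= (0.05 * X)^2
  bone <- array(rep(bone2d, Z), c(X, Y, Z)) & inner
  pan <- outer(outer((xi / 0.26)^2, ((yi + 0.05) / 0.10)^2, `+`),
               (zi / 0.30)^2, `+`) <= 1
  pan <- pan & inner & !bone
  list(body = body, inner = inner, bone = bone, pancreas = pan)
}

# Pancreas surface voxels: pancreas voxels with a 6-neighbour outside it.
.boundaryVoxels <- function(pan) {
  d <- dim(pan)
  shift <- function(a, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
    out
  }
  nOutside <- !shift(pan, 1, 0, 0) | !shift(pan, -1, 0, 0) |
    !shift(pan, 0, 1, 0) | !shift(pan, 0, -1, 0) |
    !shift(pan, 0, 0, 1) | !shift(pan, 0, 0, -1)
  which(pan & nOutside, arr.ind = TRUE)
}

#' Generate one synthetic abdominal CT phantom
#'
#' Builds a superellipse soft-tissue abdomen surrounded by a fat ring and
#' air, with a bone cylinder, an elongated pancreas ellipsoid, and `nCysts`
#' spherical near-water cysts. Attached cysts are seeded on the pancreas
#' boundary so every cyst component touches a pancreas voxel; detached
#' cysts are kept clear of the pancreas. Voxel intensities are drawn from
#' the tissue models plus global noise. Generation is fully reproducible
#' from `(spec, spec$seed)`.
#'
#' @param spec A [phantomSpec()].
#' @return List with elements `ct` ([CTVolume-class]), `labels`
#'   ([LabelVolume-class]) and `cysts` (data.frame: one row per cyst with
#'   centre, radius, risk group).
#' @examples
#' ph <- generatePhantom(phantomSpec(nCysts = 2, seed = 7))
#' ph$labels
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  gs <- spec$gridShape
  geo <- .phantomGeometry(gs)
  riskGroup <- spec$riskGroup
  if (is.null(riskGroup) && spec$nCysts > 0L)
    riskGroup <- sample(c("high", "low"), spec$nCysts, replace = TRUE)

  cysts <- NULL
  for (attempt in seq_len(100L)) {
    res <- .placeCysts(spec, geo, riskGroup)
    if (!is.null(res)) { cysts <- res; break }
  }
  if (spec$nCysts > 0L && is.null(cysts))
    stop("cyst placement failed after bounded retries; ",
         "reduce nCysts or cyst radii", call. = FALSE)

  labels <- array(0L, gs)
  labels[geo$pancreas] <- 1L
  if (spec$nCysts > 0L) labels[cysts$mask] <- 2L

  tm <- spec$tissues
  hu <- function(n) tm$mean_hu[tm$name == n]
  sdv <- function(n) tm$sd_hu[tm$name == n]
  meanMap <- array(hu("air"), gs)
  sdMap <- array(sdv("air"), gs)
  fill <- function(mask, n) {
    meanMap[mask] <<- hu(n)
    sdMap[mask] <<- sdv(n)
  }
  fill(geo$body, "fat")
  fill(geo$inner, "soft")
  fill(geo$bone, "bone")
  fill(labels == 1L, "pancreas")
  fill(labels == 2L, "cyst")
  vox <- meanMap + rnorm(length(meanMap)) * sdMap +
    rnorm(length(meanMap)) * spec$noiseSd
  dim(vox) <- gs

  info <- if (spec$nCysts > 0L) cysts$info else
    data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
               radius = numeric(0), riskGroup = character(0))
  list(ct = CTVolume(vox, spec$spacing),
       labels = LabelVolume(labels, spec$spacing),
       cysts = info)
}

# One placement attempt; NULL when constraints could not be met.
.placeCysts <- function(spec, geo, riskGroup) {
  gs <- spec$gridShape
  n <- spec$nCysts
  if (n == 0L) return(list(mask = array(FALSE, gs),
                           info = data.frame()))
  rlo <- spec$cystRadiusRange[1]; rhi <- spec$cystRadiusRange[2]
  rmid <- (rlo + rhi) / 2
  bnd <- .boundaryVoxels(geo$pancreas)
  if (nrow(bnd) == 0L) return(NULL)
  panIdx <- which(geo$pancreas, arr.ind = TRUE)
  centres <- matrix(NA_real_, n, 3)
  radii <- numeric(n)
  mask <- array(FALSE, gs)
  xs <- 1:gs[1]; ys <- 1:gs[2]; zs <- 1:gs[3]
  for (i in seq_len(n)) {
    r <- if (riskGroup[i] == "high") runif(1, rmid, rhi) else runif(1, rlo, rmid)
    placed <- FALSE
    for (try in seq_len(50L)) {
      if (spec$cystAttached) {
        ctr <- bnd[sample.int(nrow(bnd), 1L), ]
      } else {
        cand <- which(geo$inner & !geo$pancreas, arr.ind = TRUE)
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        d2pan <- min((panIdx[, 1] - ctr[1])^2 + (panIdx[, 2] - ctr[2])^2 +
                       (panIdx[, 3] - ctr[3])^2)
        if (sqrt(d2pan) < r + 3) next   # keep detached cysts clear
      }
      if (i > 1L) {
        dd <- sqrt((centres[seq_len(i - 1L), 1] - ctr[1])^2 +
                     (centres[seq_len(i - 1L), 2] - ctr[2])^2 +
                     (centres[seq_len(i - 1L), 3] - ctr[3])^2)
        if (any(dd < radii[seq_len(i - 1L)] + r + 2)) next
      }
      sph <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
                   (zs - ctr[3])^2, `+`) <= r^2
      sph <- sph & geo$inner & !geo$bone
      if (!any(sph)) next
      if (spec$cystAttached && !any(sph & geo$pancreas)) next
      if (spec$cystAttached && all(geo$pancreas[sph])) next  # must not vanish
      centres[i, ] <- ctr
      radii[i] <- r
      mask <- mask | sph
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  # cysts must form exactly n components, each (when attached) adjacent to
  # remaining pancreas voxels
  lab <- array(0L, gs); lab[geo$pancreas] <- 1L; lab[mask] <- 2L
  comp <- cpp_label_components(array(as.integer(lab == 2L), gs), gs, 26L)
  k <- max(comp)
  if (k != n) return(NULL)
  if (spec$cystAttached) {
    touch <- cpp_touching_labels(comp, array(as.integer(lab == 1L), gs),
                                 gs, 26L, k)
    if (!all(touch)) return(NULL)
  }
  list(mask = mask,
       info = data.frame(cx = centres[, 1], cy = centres[, 2],
                         cz = centres[, 3], radius = radii,
                         riskGroup = riskGroup,
                         stringsAsFactors = FALSE))
}

#' Generate a synthetic case/control cohort
#'
#' Creates `nCases` phantoms carrying cysts and `nControls` cyst-free
#' phantoms, assigns each case a cyst risk group, and stratifies the
#' train/test split by case/control status: each stratum contributes
#' `floor(trainFraction * n)` studies to the training set and the remainder
#' to the test set.
#'
#' @param nCases Number of cyst-bearing studies (>= 0).
#' @param nControls Number of control studies (>= 0).
#' @param specTemplate A [phantomSpec()] used for every study (controls get
#'   `nCysts = 0`; cases get `max(1, nCysts)` cysts).
#' @param seed Integer master seed; per-study seeds are derived from it.
#' @param trainFraction Fraction of each stratum assigned to training.
#' @return List of [StudyRecord-class] objects.
#' @examples
#' coh <- generateCohort(2, 1, phantomSpec(), seed = 3)
#' vapply(coh, isCase, logical(1))
#' @export
generateCohort <- function(nCases, nControls, specTemplate = phantomSpec(),
                           seed = 1L, trainFraction = 0.7) {
  nCases <- .assertCount(nCases, "nCases")
  nControls <- .assertCount(nControls, "nControls")
  stopifnot(inherits(specTemplate, "PhantomSpec"))
  if (trainFraction < 0 || trainFraction > 1)
    stop("trainFraction must be in [0, 1]", call. = FALSE)
  withSeed(seed, {
    n <- nCases + nControls
    seeds <- sample.int(2^30, n)
    isCaseV <- c(rep(TRUE, nCases), rep(FALSE, nControls))
    split <- character(n)
    caseIdx <- which(isCaseV); ctrlIdx <- which(!isCaseV)
    pick <- function(idx) {
      nTrain <- floor(trainFraction * length(idx))
      idx[sample.int(length(idx))][seq_len(nTrain)]
    }
    split[] <- "test"
    split[c(pick(caseIdx), pick(ctrlIdx))] <- "train"
    records <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- specTemplate
      sp$seed <- seeds[i]
      sp$nCysts <- if (isCaseV[i]) max(1L, specTemplate$nCysts) else 0L
      sp$riskGroup <- NULL
      ph <- generatePhantom(sp)
      rg <- if (isCaseV[i]) {
        # study-level risk group: highest-risk cyst wins
        if (any(ph$cysts$riskGroup == "high")) "high" else "low"
      } else "none"
      records[[i]] <- StudyRecord(
        studyId = sprintf("%s-%03d", if (isCaseV[i]) "case" else "control",
                          if (isCaseV[i]) i else i - nCases),
        ct = ph$ct, labels = ph$labels, isCase = isCaseV[i],
        riskGroup = rg, split = split[i])
    }
    records
  })
}

#' Write a cohort to disk as NIfTI pairs plus a manifest
#'
#' Writes `<id>_ct.nii.gz` and `<id>_seg.nii.gz` per study and a
#' `manifest.csv` with columns `study_id`, `ct_path`, `seg_path`,
#' `is_case`, `risk_group`, `split`.
#'
#' @param records List of [StudyRecord-class] objects.
#' @param dir Output directory (created if absent).
#' @return Path to the manifest CSV, invisibly.
#' @export
writeCohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    ctPath <- file.path(dir, paste0(studyId(r), "_ct.nii.gz"))
    segPath <- file.path(dir, paste0(studyId(r), "_seg.nii.gz"))
    writeVolume(r@ct, ctPath)
    if (!is.null(r@labels)) writeVolume(r@labels, segPath) else segPath <- ""
    data.frame(study_id = studyId(r), ct_path = ctPath, seg_path = segPath,
               is_case = isCase(r), risk_group = riskGroup(r),
               split = r@split, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
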