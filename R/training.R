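#' @include agnet.R preprocess.R
NULL

#' Training configuration
#'
#' Clinical-scale defaults: 700 epochs, batch size 4, Adam from an
#' initial learning rate of 1e-4, learning-rate reduction after a
#' 30-epoch validation plateau, and random 160 x 160 in-plane patches of
#' the central crop. A plateau multiplies the rate by `lrFactor`
#' (default 0.1) down to the terminal rate `lrFloor` (1e-6). Desk-scale
#' tests override `epochs`, `patchInplane`, `patchDepth` and the network
#' size.
#'
#' @param epochs Number of training epochs.
#' @param batchSize Patches per optimization step.
#' @param lrInitial Initial Adam learning rate.
#' @param plateauPatience Epochs without validation improvement before the
#'   learning rate is reduced.
#' @param lrFloor Minimum learning rate.
#' @param lrFactor Multiplicative reduction on plateau.
#' @param patchInplane In-plane patch size in voxels.
#' @param patchDepth Patch depth in slices (1 for 2D networks).
#' @param stepsPerEpoch Optimization steps per epoch.
#' @param valFraction Fraction of training studies held out to drive the
#'   plateau criterion (at least one study when there are two or more;
#'   with a single study, training loss drives the plateau).
#' @param fgBias Probability that a sampled patch is forced to contain a
#'   foreground (pancreas or cyst) voxel, countering the extreme class
#'   imbalance of small lesions.
#' @param diceBackground Include the background class in the optimized
#'   Dice mean (default `TRUE`). Background supervision is what teaches
#'   the network that air, fat and soft tissue are background; without
#'   it the rare classes leak into unsupervised regions. (Safe only
#'   together with activation normalization — see
#'   [agnetConfig()]'s `instanceNorm`.)
#' @param gradClip Global-norm gradient clipping threshold (`Inf`
#'   disables). Soft-Dice gradients spike on patches where a class is
#'   nearly absent; unclipped spikes can saturate the softmax
#'   irrecoverably early in training.
#' @param seed Integer seed controlling initialization and sampling.
#' @return Named list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 700L, batchSize = 4L, lrInitial = 1e-4,
                        plateauPatience = 30L, lrFloor = 1e-6,
                        lrFactor = 0.1, patchInplane = 160L,
                        patchDepth = 16L, stepsPerEpoch = 10L,
                        valFraction = 0.1, fgBias = 0.5,
                        diceBackground = TRUE, gradClip = 3,
                        seed = 42L) {
  if (lrInitial <= 0 || lrFloor <= 0 || lrFloor >= lrInitial)
    stop("need 0 < lrFloor < lrInitial", call. = FALSE)
  if (lrFactor <= 0 || lrFactor >= 1)
    stop("lrFactor must be in (0, 1)", call. = FALSE)
  if (fgBias < 0 || fgBias > 1) stop("fgBias must be in [0, 1]", call. = FALSE)
  structure(list(epochs = .assertCount(epochs, "epochs", 1L),
                 batchSize = .assertCount(batchSize, "batchSize", 1L),
                 lrInitial = lrInitial,
                 plateauPatience = .assertCount(plateauPatience,
                                                "plateauPatience", 1L),
                 lrFloor = lrFloor, lrFactor = lrFactor,
                 patchInplane = .assertCount(patchInplane, "patchInplane", 1L),
                 patchDepth = .assertCount(patchDepth, "patchDepth", 1L),
                 stepsPerEpoch = .assertCount(stepsPerEpoch, "stepsPerEpoch", 1L),
                 valFraction = valFraction, fgBias = fgBias,
                 diceBackground = .assertFlag(diceBackground,
                                               "diceBackground"),
                 gradClip = gradClip,
                 seed = .assertCount(seed, "seed")),
            class = "TrainConfig")
}

.softmaxMat <- function(z) {
  m <- z[, 1]
  for (c in seq_len(ncol(z))[-1]) m <- pmax(m, z[, c])
  e <- exp(z - m)
  e / rowSums(e)
}

#' Multiclass soft-Dice loss
#'
#' `1 - mean_c [(2 sum p_c y_c + eps) / (sum p_c + sum y_c + eps)]` over
#' the class set, where `p` are per-class probabilities and `y` the
#' one-hot ground truth. The loss lies in \[0, 1\]: 0 for a perfect
#' one-hot match, 1 for total disjointness (as `eps -> 0`), and it is
#' invariant under a permutation of classes applied jointly to `probs`
#' and `labels`.
#'
#' @param probs 4D (x, y, z, class) probability array or
#'   [ProbabilityVolume-class].
#' @param labels Integer 3D array / [LabelVolume-class] of class indices
#'   (0-based).
#' @param eps Smoothing constant added to numerator and denominator.
#' @param includeBackground Include class 0 in the mean.
#' @return Scalar loss.
#' @examples
#' p <- array(0, c(2, 1, 1, 2)); p[1, , , 1] <- 1; p[2, , , 1] <- 1
#' y <- array(c(0L, 1L), c(2, 1, 1))
#' diceLoss(p, y, eps = 0)  # 2/3
#' @export
diceLoss <- function(probs, labels, eps = 1e-5, includeBackground = TRUE) {
  p <- if (is(probs, "ProbabilityVolume")) voxelData(probs) else probs
  y <- if (is(labels, "LabelVolume")) voxelData(labels) else labels
  if (length(dim(p)) != 4L)
    stop("probs must be 4D (x, y, z, class)", call. = FALSE)
  if (!all(dim(p)[1:3] == dim(y)))
    stop("probs and labels shapes disagree", call. = FALSE)
  nc <- dim(p)[4]
  if (any(y < 0 | y >= nc)) stop("labels outside class range", call. = FALSE)
  V <- prod(dim(y))
  pm <- matrix(p, V, nc)
  ym <- matrix(0, V, nc)
  ym[cbind(seq_len(V), as.vector(y) + 1L)] <- 1
  cls <- if (includeBackground) seq_len(nc) else seq_len(nc)[-1]
  num <- 2 * colSums(pm * ym) + eps
  den <- colSums(pm) + colSums(ym) + eps
  1 - mean((num / den)[cls])
}

# Soft-Dice loss and gradient w.r.t. logits (softmax folded in).
# presentOnly averages only over classes present in the ground truth
# (falling back to background for foreground-free patches): absent
# classes otherwise contribute near-zero Dice whose gradient drives the
# softmax into saturation on small patches.
.diceFromLogits <- function(logits, labels, eps = 1e-5,
                            includeBackground = TRUE, presentOnly = FALSE) {
  nc <- dim(logits)[4]
  V <- prod(dim(logits)[1:3])
  pm <- .softmaxMat(matrix(logits, V, nc))
  ym <- matrix(0, V, nc)
  ym[cbind(seq_len(V), as.vector(labels) + 1L)] <- 1
  cls <- if (includeBackground) seq_len(nc) else seq_len(nc)[-1]
  if (presentOnly) {
    cls <- intersect(cls, which(colSums(ym) > 0))
    if (length(cls) == 0L) cls <- 1L
  }
  num <- 2 * colSums(pm * ym) + eps
  den <- colSums(pm) + colSums(ym) + eps
  dice <- num / den
  loss <- 1 - mean(dice[cls])
  gp <- matrix(0, V, nc)
  for (c in cls)
    gp[, c] <- -(2 * ym[, c] / den[c] - num[c] / den[c]^2) / length(cls)
  gz <- pm * (gp - rowSums(gp * pm))
  list(loss = loss, glogits = array(gz, dim(logits)), dice = dice)
}

#' Sample training patches from a volume
#'
#' Draws `n` axis-aligned patches of `patchInplane^2 x patchDepth` voxels
#' with uniformly distributed in-bounds offsets. With probability
#' `cfg$fgBias` (and labels present) a patch is instead anchored on a
#' uniformly chosen foreground voxel: the offset is drawn uniformly among
#' all in-bounds offsets whose window contains that voxel. Sampling is
#' reproducible via `seed`.
#'
#' @param ct 3D array (or [CTVolume-class]) of normalized intensities.
#' @param labels Optional aligned 3D integer array / [LabelVolume-class].
#' @param cfg A [trainConfig()] (patch geometry and `fgBias`).
#' @param n Number of patches.
#' @param seed Optional integer seed.
#' @return List of lists with `patch`, `labels` (or `NULL`) and 0-based
#'   `offset`.
#' @export
samplePatches <- function(ct, labels = NULL, cfg = trainConfig(), n = 1L,
                          seed = NULL) {
  vol <- if (is(ct, "CTVolume")) voxelData(ct) else ct
  lab <- if (is(labels, "LabelVolume")) voxelData(labels) else labels
  d <- dim(vol)
  ps <- c(cfg$patchInplane, cfg$patchInplane, cfg$patchDepth)
  if (any(d < ps))
    stop("volume ", paste(d, collapse = "x"), " smaller than patch ",
         paste(ps, collapse = "x"), call. = FALSE)
  draw <- function() {
    maxOff <- d - ps
    if (!is.null(lab) && cfg$fgBias > 0 && runif(1) < cfg$fgBias &&
        any(lab > 0L)) {
      # class-balanced anchoring: choose a present foreground class
      # uniformly, then a voxel of that class; small lesions are anchored
      # as often as the much larger pancreas
      present <- intersect(1:2, unique(as.vector(lab[lab > 0L])))
      cl <- if (length(present) == 1L) present else
        present[sample.int(length(present), 1L)]
      fg <- which(lab == cl, arr.ind = TRUE)
      v <- fg[sample.int(nrow(fg), 1L), ] - 1L   # 0-based voxel
      off <- integer(3)
      for (a in 1:3) {
        lo <- max(0L, v[a] - ps[a] + 1L)
        hi <- min(maxOff[a], v[a])
        off[a] <- if (hi > lo) sample(lo:hi, 1L) else lo
      }
    } else {
      off <- vapply(1:3, function(a)
        sample.int(maxOff[a] + 1L, 1L) - 1L, integer(1))
    }
    idx <- lapply(1:3, function(a) off[a] + seq_len(ps[a]))
    list(patch = vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         labels = if (is.null(lab)) NULL else
           lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         offset = off)
  }
  if (!is.null(seed)) withSeed(seed, replicate(n, draw(), simplify = FALSE))
  else replicate(n, draw(), simplify = FALSE)
}

.adamInit <- function(params) {
  zl <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zl, v = zl, t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the attention-gate U-Net on a cohort
#'
#' Preprocesses every training study (soft-tissue windowing, central
#' crop), holds out `valFraction` of the training studies to drive the
#' plateau criterion, initializes the network with Kaiming weights and
#' optimizes the multiclass soft-Dice loss with Adam. The learning rate is
#' multiplied by `lrFactor` whenever the validation loss has not improved
#' for `plateauPatience` consecutive epochs, never dropping below
#' `lrFloor`. Fully reproducible from the seeds in the configs.
#'
#' @param cohort List of [StudyRecord-class] objects; records with
#'   `split == "train"` are used (all records when none is marked).
#' @param agnetCfg An [agnetConfig()].
#' @param trainCfg A [trainConfig()].
#' @param preCfg A [preprocessConfig()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` ([AGNetModel-class]) and `history`
#'   (data.frame: epoch, trainLoss, valLoss, lr).
#' @export
trainAGNet <- function(cohort, agnetCfg = agnetConfig(),
                       trainCfg = trainConfig(),
                       preCfg = preprocessConfig(), verbose = FALSE) {
  splits <- vapply(cohort, function(r) r@split, character(1))
  train <- cohort[splits == "train"]
  if (length(train) == 0L) train <- cohort
  if (length(train) == 0L)
    stop("empty training set", call. = FALSE)
  prepped <- lapply(train, function(r) {
    vol <- voxelData(centralCrop(softTissueNormalize(r@ct, preCfg), preCfg))
    lab <- if (!is.null(r@labels)) voxelData(centralCrop(r@labels, preCfg))
    list(vol = vol, lab = lab)
  })
  if (any(vapply(prepped, function(p) is.null(p$lab), logical(1))))
    stop("all training studies need label volumes", call. = FALSE)

  withSeed(trainCfg$seed, {
    nVal <- if (length(prepped) >= 2L)
      max(1L, round(trainCfg$valFraction * length(prepped))) else 0L
    valIdx <- if (nVal > 0L) sample.int(length(prepped), nVal) else integer(0)
    trIdx <- setdiff(seq_along(prepped), valIdx)
    if (length(trIdx) == 0L) trIdx <- seq_along(prepped)

    model <- agnetInit(agnetCfg, seed = sample.int(2^30, 1))
    params <- model@params
    cfg <- model@config
    state <- .adamInit(params)
    lr <- trainCfg$lrInitial
    ps <- c(trainCfg$patchInplane, trainCfg$patchInplane, trainCfg$patchDepth)

    centerPatch <- function(p) {
      d <- dim(p$vol)
      off <- pmax(floor((d - ps) / 2), 0)
      idx <- lapply(1:3, function(a) off[a] + seq_len(ps[a]))
      list(patch = p$vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
           labels = p$lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
    }
    valPatches <- lapply(prepped[valIdx], centerPatch)

    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valLoss = numeric(0), lr = numeric(0))
    best <- Inf
    sincePlateau <- 0L
    for (ep in seq_len(trainCfg$epochs)) {
      stepLosses <- numeric(trainCfg$stepsPerEpoch)
      for (st in seq_len(trainCfg$stepsPerEpoch)) {
        gSum <- NULL
        lsum <- 0
        for (b in seq_len(trainCfg$batchSize)) {
          p <- prepped[[trIdx[sample.int(length(trIdx), 1L)]]]
          pt <- samplePatches(p$vol, p$lab, trainCfg, n = 1L)[[1]]
          fw <- .agnetForwardImpl(params, cfg, pt$patch, keepCache = TRUE)
          dl <- .diceFromLogits(fw$logits, pt$labels,
                                includeBackground = trainCfg$diceBackground,
                                presentOnly = TRUE)
          lsum <- lsum + dl$loss
          gr <- .agnetBackward(params, cfg, fw$cache, dl$glogits)
          if (is.null(gSum)) gSum <- gr
          else for (nm in names(gSum)) gSum[[nm]] <- gSum[[nm]] + gr[[nm]]
        }
        for (nm in names(gSum))
          gSum[[nm]] <- gSum[[nm]] / trainCfg$batchSize
        if (is.finite(trainCfg$gradClip)) {
          gn <- sqrt(sum(vapply(gSum, function(g) sum(g * g), numeric(1))))
          if (gn > trainCfg$gradClip)
            for (nm in names(gSum))
              gSum[[nm]] <- gSum[[nm]] * (trainCfg$gradClip / gn)
        }
        up <- .adamStep(params, gSum, state, lr)
        params <- up$params
        state <- up$state
        stepLosses[st] <- lsum / trainCfg$batchSize
      }
      trainLoss <- mean(stepLosses)
      valLoss <- if (length(valPatches) > 0L) {
        mean(vapply(valPatches, function(vp) {
          fw <- .agnetForwardImpl(params, cfg, vp$patch)
          .diceFromLogits(fw$logits, vp$labels,
                          includeBackground = trainCfg$diceBackground,
                          presentOnly = TRUE)$loss
        }, numeric(1)))
      } else trainLoss
      history <- rbind(history,
                       data.frame(epoch = ep, trainLoss = trainLoss,
                                  valLoss = valLoss, lr = lr))
      if (valLoss < best - 1e-5) {
        best <- valLoss
        sincePlateau <- 0L
      } else {
        sincePlateau <- sincePlateau + 1L
        if (sincePlateau >= trainCfg$plateauPatience) {
          lr <- max(lr * trainCfg$lrFactor, trainCfg$lrFloor)
          sincePlateau <- 0L
        }
      }
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f lr %.2g",
                        ep, trainLoss, valLoss, lr))
    }
    list(model = new("AGNetModel", config = cfg, params = params),
         history = history)
  })
}

#' Save a trained model to a checkpoint file
#' @param model An [AGNetModel-class].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "AGNetModel"))
  saveRDS(list(config = model@config, params = model@params,
               package = "PCLseg",
               version = as.character(utils::packageVersion("PCLseg"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [saveCheckpoint()].
#' @return An [AGNetModel-class].
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$params) || is.null(x$config))
    stop("not a model checkpoint: ", path, call. = FALSE)
  new("AGNetModel", config = x$config, params = x$params)
}
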