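#' @include volumes.R
NULL

#' Attention-gate U-Net architecture configuration
#'
#' The segmentation network is a U-Net: an encoder that halves the spatial
#' grid with factor-2 max-pooling while doubling channels at each scale,
#' and a decoder that upsamples trilinearly (bilinearly in 2D) by the same
#' factor. Every decoder stage receives its encoder skip connection
#' through an additive attention gate (see [attentionGate()]), which
#' suppresses skip activations irrelevant to the focus region.
#'
#' @param nClasses Number of output classes (>= 2; default 3:
#'   background/pancreas/cyst).
#' @param nScales Number of resolution scales (>= 2). The clinical-scale
#'   default is 4; the package's desk-scale tests use 2.
#' @param baseChannels Channels at the finest scale; doubled per scale.
#' @param spatialDims 3 for volumetric slabs (3x3x3 kernels, trilinear
#'   upsampling), 2 for per-slice processing (3x3x1 kernels, bilinear).
#' @param multidimAttention Logical; when `TRUE` the gate produces one
#'   attention map per class (combined by averaging before gating), when
#'   `FALSE` a single map.
#' @param instanceNorm Logical; insert channel-wise instance
#'   normalization between each 3x3(x3) convolution and its ReLU.
#'   Normalization bounds the activation (and hence logit) scale, which
#'   the scale-free soft-Dice loss otherwise inflates without limit
#'   until the softmax saturates and small classes die; it is standard
#'   in this network family.
#' @return Named list of class `"AGNetConfig"`.
#' @examples
#' agnetConfig(nScales = 2, baseChannels = 8)
#' @export
agnetConfig <- function(nClasses = 3L, nScales = 4L, baseChannels = 16L,
                        spatialDims = 3L, multidimAttention = TRUE,
                        instanceNorm = TRUE) {
  nClasses <- .assertCount(nClasses, "nClasses", min = 2L)
  nScales <- .assertCount(nScales, "nScales", min = 2L)
  baseChannels <- .assertCount(baseChannels, "baseChannels", min = 1L)
  if (!spatialDims %in% c(2L, 3L))
    stop("spatialDims must be 2 or 3", call. = FALSE)
  structure(list(nClasses = nClasses, nScales = nScales,
                 baseChannels = baseChannels,
                 spatialDims = as.integer(spatialDims),
                 multidimAttention = .assertFlag(multidimAttention,
                                                 "multidimAttention"),
                 instanceNorm = .assertFlag(instanceNorm, "instanceNorm")),
            class = "AGNetConfig")
}

.poolFactor <- function(cfg) {
  if (cfg$spatialDims == 3L) c(2L, 2L, 2L) else c(2L, 2L, 1L)
}

.kernelDepth <- function(cfg) if (cfg$spatialDims == 3L) 3L else 1L

# channels at scale l
.chan <- function(cfg, l) cfg$baseChannels * 2L^(l - 1L)

.convF <- function(x, w, b) cpp_conv3d_fwd(x, w, b, dim(x), dim(w))

.convB <- function(x, w, gy, needGx = TRUE)
  cpp_conv3d_bwd(x, w, gy, dim(x), dim(w), needGx)

.kaiming <- function(dims) {
  fanIn <- prod(dims[-length(dims)])
  array(rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
}

# Channel-wise instance normalization (one sample): normalize each
# channel over its spatial grid, then scale/shift by learnable gamma/beta.
.inF <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  X <- matrix(x, prod(d[1:3]), d[4])
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xh <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xh, 2, g, `*`), 2, b, `+`)
  list(y = array(y, d), xh = xh, inv = inv)
}

.inB <- function(gy4, cache, g) {
  d <- dim(gy4)
  gy <- matrix(gy4, prod(d[1:3]), d[4])
  gg <- colSums(gy * cache$xh)
  gb <- colSums(gy)
  gxh <- sweep(gy, 2, g, `*`)
  gx <- sweep(gxh, 2, colMeans(gxh)) -
    sweep(cache$xh, 2, colMeans(gxh * cache$xh), `*`)
  gx <- sweep(gx, 2, cache$inv, `*`)
  list(gx = array(gx, d), gg = gg, gb = gb)
}

#' Initialize an attention-gate U-Net with Kaiming weights
#'
#' Convolution weights are drawn from the Kaiming (He) normal distribution
#' `N(0, sqrt(2 / fan_in))` matched to the ReLU nonlinearity; biases start
#' at zero.
#'
#' @param cfg An [agnetConfig()].
#' @param seed Integer seed for the weight draw.
#' @return An [AGNetModel-class].
#' @examples
#' m <- agnetInit(agnetConfig(nScales = 2, baseChannels = 4), seed = 1)
#' nParams(m)
#' @export
agnetInit <- function(cfg = agnetConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "AGNetConfig"))
  withSeed(seed, {
    kz <- .kernelDepth(cfg)
    S <- cfg$nScales
    natt <- if (cfg$multidimAttention) cfg$nClasses else 1L
    p <- list()
    addNorm <- function(p, stem, f) {
      if (cfg$instanceNorm) {
        p[[paste0(stem, ".ing")]] <- rep(1, f)
        p[[paste0(stem, ".inb")]] <- numeric(f)
      }
      p
    }
    for (l in seq_len(S)) {
      cin <- if (l == 1L) 1L else .chan(cfg, l - 1L)
      f <- .chan(cfg, l)
      p[[sprintf("enc%d.c1.w", l)]] <- .kaiming(c(3L, 3L, kz, cin, f))
      p[[sprintf("enc%d.c1.b", l)]] <- numeric(f)
      p <- addNorm(p, sprintf("enc%d.c1", l), f)
      p[[sprintf("enc%d.c2.w", l)]] <- .kaiming(c(3L, 3L, kz, f, f))
      p[[sprintf("enc%d.c2.b", l)]] <- numeric(f)
      p <- addNorm(p, sprintf("enc%d.c2", l), f)
    }
    for (l in seq_len(S - 1L)) {
      f <- .chan(cfg, l)
      fg <- .chan(cfg, l + 1L)
      p[[sprintf("att%d.wx", l)]] <- .kaiming(c(1L, 1L, 1L, f, f))
      p[[sprintf("att%d.bx", l)]] <- numeric(f)
      p[[sprintf("att%d.wg", l)]] <- .kaiming(c(1L, 1L, 1L, fg, f))
      p[[sprintf("att%d.psi", l)]] <- .kaiming(c(1L, 1L, 1L, f, natt))
      p[[sprintf("att%d.psib", l)]] <- numeric(natt)
      p[[sprintf("dec%d.c1.w", l)]] <- .kaiming(c(3L, 3L, kz, fg + f, f))
      p[[sprintf("dec%d.c1.b", l)]] <- numeric(f)
      p <- addNorm(p, sprintf("dec%d.c1", l), f)
      p[[sprintf("dec%d.c2.w", l)]] <- .kaiming(c(3L, 3L, kz, f, f))
      p[[sprintf("dec%d.c2.b", l)]] <- numeric(f)
      p <- addNorm(p, sprintf("dec%d.c2", l), f)
    }
    p[["final.w"]] <- .kaiming(c(1L, 1L, 1L, cfg$baseChannels, cfg$nClasses))
    p[["final.b"]] <- numeric(cfg$nClasses)
    new("AGNetModel", config = unclass(cfg), params = p)
  })
}

#' @rdname nParams
#' @export
setMethod("nParams", "AGNetModel", function(object)
  sum(vapply(object@params, length, integer(1))))

setMethod("show", "AGNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "AGNetModel: %dD attention-gate U-Net, %d scales, %d base channels,\n  %d classes, %s attention, %d parameters\n",
    cfg$spatialDims, cfg$nScales, cfg$baseChannels, cfg$nClasses,
    if (cfg$multidimAttention) "per-class" else "single-map",
    nParams(object)))
})

#' Additive attention gate
#'
#' Computes per-position attention coefficients from skip features `x` and
#' a gating signal `g` already resampled to the same grid:
#' `alpha = sigmoid(psi(relu(Wx x + Wg g + b)))`, and returns the gated
#' skip `alpha * x` (same shape as `x`). With per-class attention, `psi`
#' emits one map per class and the maps are averaged before gating. The
#' gating signal comes from the coarser decoder stage and carries the
#' contextual information that selects focus regions.
#'
#' @param x 4D (x, y, z, channels) skip feature map.
#' @param g 4D gating feature map on the same spatial grid.
#' @param params Named list with elements `wx` (1x1x1 conv weights,
#'   channels-of-x to F_int), `bx`, `wg` (channels-of-g to F_int), `psi`
#'   (F_int to number of attention maps) and `psib`.
#' @return List with `gated` (alpha * x), `alpha` (combined map,
#'   4D with one channel) and `att` (raw per-map sigmoid outputs).
#' @examples
#' p <- list(wx = array(1, c(1, 1, 1, 1, 1)), bx = 0,
#'           wg = array(1, c(1, 1, 1, 1, 1)),
#'           psi = array(1, c(1, 1, 1, 1, 1)), psib = 0)
#' attentionGate(array(2, c(1, 1, 1, 1)), array(3, c(1, 1, 1, 1)), p)$gated
#' @export
attentionGate <- function(x, g, params) {
  if (length(dim(x)) != 4L || length(dim(g)) != 4L)
    stop("x and g must be 4D (x, y, z, channel) arrays", call. = FALSE)
  if (!all(dim(x)[1:3] == dim(g)[1:3]))
    stop("x and g must share a spatial grid; resample g first", call. = FALSE)
  gt <- .gateForward(x, g, params)
  list(gated = gt$gated, alpha = gt$alpha, att = gt$att)
}

.gateForward <- function(s, gup, p) {
  a1 <- .convF(s, p$wx, p$bx)
  a2 <- .convF(gup, p$wg, numeric(dim(p$wg)[5]))
  pre <- a1 + a2
  q <- pre * (pre > 0)
  t <- .convF(q, p$psi, p$psib)
  att <- 1 / (1 + exp(-t))
  natt <- dim(att)[4]
  alpha <- if (natt > 1L) {
    array(rowMeans(matrix(att, prod(dim(att)[1:3]), natt)),
          c(dim(att)[1:3], 1L))
  } else att
  gated <- s * as.vector(alpha)
  list(gated = gated, alpha = alpha, att = att, q = q, mq = pre > 0, s = s,
       gup = gup)
}

.gateParams <- function(params, l) {
  list(wx = params[[sprintf("att%d.wx", l)]],
       bx = params[[sprintf("att%d.bx", l)]],
       wg = params[[sprintf("att%d.wg", l)]],
       psi = params[[sprintf("att%d.psi", l)]],
       psib = params[[sprintf("att%d.psib", l)]])
}

.checkPatchDims <- function(cfg, d) {
  need <- 2L^(cfg$nScales - 1L)
  axes <- if (cfg$spatialDims == 3L) 1:3 else 1:2
  if (any(d[axes] %% need != 0L))
    stop("patch dimensions (", paste(d, collapse = "x"), ") must be ",
         "divisible by ", need, " (= 2^(nScales-1)) along ",
         if (cfg$spatialDims == 3L) "all three axes" else "both in-plane axes",
         call. = FALSE)
}

# Full forward pass. Returns logits and, when keepCache, every
# intermediate needed by .agnetBackward.
.agnetForwardImpl <- function(params, cfg, x, keepCache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  .checkPatchDims(cfg, dim(x))
  S <- cfg$nScales
  pool <- .poolFactor(cfg)
  useIN <- isTRUE(cfg$instanceNorm)
  # conv -> (instance norm) -> ReLU, with everything backward needs
  convStage <- function(x, stem) {
    a <- .convF(x, params[[paste0(stem, ".w")]],
                params[[paste0(stem, ".b")]])
    nrm <- NULL
    if (useIN) {
      nrm <- .inF(a, params[[paste0(stem, ".ing")]],
                  params[[paste0(stem, ".inb")]])
      a <- nrm$y
      nrm$y <- NULL
    }
    list(r = a * (a > 0), m = a > 0, nrm = nrm, xin = x)
  }
  skips <- vector("list", S)
  encCache <- vector("list", S)
  poolCache <- vector("list", S)
  h <- x
  for (l in seq_len(S)) {
    if (l > 1L) {
      mp <- cpp_maxpool_fwd(h, dim(h), pool)
      poolCache[[l]] <- list(idx = mp$idx, indim = dim(h))
      h <- mp$y
    }
    s1 <- convStage(h, sprintf("enc%d.c1", l))
    s2 <- convStage(s1$r, sprintf("enc%d.c2", l))
    if (keepCache) encCache[[l]] <- list(c1 = s1, c2 = s2)
    skips[[l]] <- s2$r
    h <- s2$r
  }
  d <- skips[[S]]
  decCache <- vector("list", S)
  for (l in seq.int(S - 1L, 1L)) {
    gup <- cpp_upsample_fwd(d, dim(d), pool)
    s <- skips[[l]]
    gt <- .gateForward(s, gup, .gateParams(params, l))
    cat4 <- array(c(gup, gt$gated),
                  c(dim(s)[1:3], dim(gup)[4] + dim(s)[4]))
    s1 <- convStage(cat4, sprintf("dec%d.c1", l))
    s2 <- convStage(s1$r, sprintf("dec%d.c2", l))
    if (keepCache) decCache[[l]] <- list(ddim = dim(d), gate = gt,
                                         c1 = s1, c2 = s2)
    d <- s2$r
  }
  logits <- .convF(d, params[["final.w"]], params[["final.b"]])
  if (!keepCache) return(list(logits = logits))
  list(logits = logits,
       cache = list(enc = encCache, dec = decCache, pools = poolCache,
                    dtop = d))
}

#' Forward pass of the attention-gate U-Net
#'
#' Maps a normalized patch (values in \[0, 1\]) to per-class logits with
#' the patch's spatial shape. Patch dimensions must be divisible by
#' `2^(nScales - 1)` along the pooled axes (all three in 3D mode, the two
#' in-plane axes in 2D mode); indivisible patches are an error rather than
#' silently padded. The pass is deterministic given fixed parameters.
#'
#' @param model An [AGNetModel-class].
#' @param patch 3D array (or 4D with one channel) of normalized values.
#' @return 4D (x, y, z, class) array of logits.
#' @export
agnetForward <- function(model, patch) {
  stopifnot(is(model, "AGNetModel"))
  .agnetForwardImpl(model@params, model@config, patch)$logits
}

# Backpropagate dLoss/dlogits through the cached forward pass; returns a
# named list of parameter gradients aligned with model params.
.agnetBackward <- function(params, cfg, cache, glogits) {
  S <- cfg$nScales
  pool <- .poolFactor(cfg)
  useIN <- isTRUE(cfg$instanceNorm)
  grads <- list()
  # adjoint of convStage: ReLU mask -> (instance norm) -> convolution
  stageB <- function(gr, stem, sc, needGx = TRUE) {
    g <- gr * sc$m
    if (useIN) {
      ib <- .inB(g, sc$nrm, params[[paste0(stem, ".ing")]])
      grads[[paste0(stem, ".ing")]] <<- ib$gg
      grads[[paste0(stem, ".inb")]] <<- ib$gb
      g <- ib$gx
    }
    cb <- .convB(sc$xin, params[[paste0(stem, ".w")]], g, needGx)
    grads[[paste0(stem, ".w")]] <<- cb$gw
    grads[[paste0(stem, ".b")]] <<- cb$gb
    cb$gx
  }
  cb <- .convB(cache$dtop, params[["final.w"]], glogits)
  grads[["final.w"]] <- cb$gw
  grads[["final.b"]] <- cb$gb
  gd <- cb$gx
  gskip <- vector("list", S)
  for (l in seq_len(S - 1L)) {
    dc <- cache$dec[[l]]
    g1 <- stageB(gd, sprintf("dec%d.c2", l), dc$c2)
    gcat <- stageB(g1, sprintf("dec%d.c1", l), dc$c1)
    fg <- dim(dc$gate$gup)[4]
    ggup <- gcat[, , , seq_len(fg), drop = FALSE]
    ggated <- gcat[, , , fg + seq_len(dim(gcat)[4] - fg), drop = FALSE]
    gb <- .gateBackward(dc$gate, .gateParams(params, l), ggated)
    for (nm in names(gb$grads))
      grads[[sprintf("att%d.%s", l, nm)]] <- gb$grads[[nm]]
    gskip[[l]] <- gb$gs
    gd <- cpp_upsample_bwd(ggup + gb$ggup, dc$ddim, pool)
  }
  gcarry <- NULL
  for (l in seq.int(S, 1L)) {
    gr2 <- if (l == S) gd else gskip[[l]] + gcarry
    ec <- cache$enc[[l]]
    g1 <- stageB(gr2, sprintf("enc%d.c2", l), ec$c2)
    gh <- stageB(g1, sprintf("enc%d.c1", l), ec$c1, needGx = l > 1L)
    if (l > 1L) {
      pc <- cache$pools[[l]]
      gcarry <- cpp_maxpool_bwd(gh, pc$idx, pc$indim)
    }
  }
  grads
}

.gateBackward <- function(gt, p, ggated) {
  s <- gt$s
  d3 <- dim(s)[1:3]
  nvox <- prod(d3)
  fs <- dim(s)[4]
  natt <- dim(gt$att)[4]
  gsA <- ggated * as.vector(gt$alpha)
  galpha <- array(rowSums(matrix(ggated * s, nvox, fs)), c(d3, 1L))
  gatt <- if (natt > 1L)
    array(rep(as.vector(galpha) / natt, natt), c(d3, natt))
  else galpha
  gtPre <- gatt * gt$att * (1 - gt$att)
  cbp <- .convB(gt$q, p$psi, gtPre)
  gpre <- cbp$gx * gt$mq
  cbx <- .convB(s, p$wx, gpre)
  cbg <- .convB(gt$gup, p$wg, gpre)
  list(gs = gsA + cbx$gx, ggup = cbg$gx,
       grads = list(wx = cbx$gw, bx = cbx$gb, wg = cbg$gw,
                    psi = cbp$gw, psib = cbp$gb))
}
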