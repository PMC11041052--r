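# Hand-built models with exactly known forward maps let the inference
# machinery be checked against closed-form expectations.
#
# constModel: logits are the final-layer biases, independent of input.
# linModel: logits of class `cls` equal the input convolved with `k1`
#   (identity by default), realised by threading a single nonnegative
#   path through encoder, open attention gate and decoder (all inputs
#   are >= 0, so every ReLU on the path is the identity).
constModel <- function(values, nClasses = 3) {
  m <- agnetInit(agnetConfig(nClasses = nClasses, nScales = 2,
                             baseChannels = 2, instanceNorm = FALSE),
                 seed = 1)
  for (nm in names(m@params)) m@params[[nm]][] <- 0
  m@params[["final.b"]] <- values
  m
}

linModel <- function(nClasses = 2, cls = 2, k1 = NULL) {
  m <- agnetInit(agnetConfig(nClasses = nClasses, nScales = 2,
                             baseChannels = 2, instanceNorm = FALSE),
                 seed = 1)
  for (nm in names(m@params)) m@params[[nm]][] <- 0
  if (is.null(k1)) m@params[["enc1.c1.w"]][2, 2, 2, 1, 1] <- 1
  else m@params[["enc1.c1.w"]][, , 2, 1, 1] <- k1
  m@params[["enc1.c2.w"]][2, 2, 2, 1, 1] <- 1
  m@params[["att1.psib"]][] <- 50          # gate wide open: alpha ~ 1
  m@params[["dec1.c1.w"]][2, 2, 2, 5, 1] <- 1  # first gated-skip channel
  m@params[["dec1.c2.w"]][2, 2, 2, 1, 1] <- 1
  m@params[["final.w"]][1, 1, 1, 1, cls] <- 1
  m
}

test_that("the default TTA set is the clinical quartet", {
  tta <- defaultTTA()
  expect_length(tta, 4)
  kinds <- vapply(tta, function(t) t$kind, character(1))
  mags <- vapply(tta, function(t) t$magnitude, numeric(1))
  expect_equal(kinds, c("rotation", "rotation", "translation", "translation"))
  expect_equal(mags, c(7, -11, 5, 10))
  expect_lt(mags[1] * mags[2], 0)  # rotations have opposite signs
})

test_that("every default transform inverts to identity on a smooth field", {
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:4)
  v <- array(sin(g$x / 6) * cos(g$y / 5) + 0.2 * sin(g$z), c(32, 32, 4))
  for (t in defaultTTA()) {
    fw <- applyTransform(v, t)
    bk <- applyTransform(fw$data, invertTransform(t))
    core <- array(rep(fw$valid * bk$valid, 4), dim(v)) > 0
    core[c(1:2, 31:32), , ] <- FALSE
    core[, c(1:2, 31:32), ] <- FALSE
    expect_lt(max(abs(bk$data - v)[core]),
              if (t$kind == "translation") 1e-12 else 0.05)
  }
})

test_that("sliding-window inference covers and averages correctly", {
  m <- constModel(c(0.5, 1.5, -2))
  v <- array(runif(16 * 16 * 8), c(16, 16, 8))
  lg <- slidingWindowInfer(m, v, patchSize = c(16, 16, 8))
  expect_equal(dim(lg), c(16, 16, 8, 3))
  expect_equal(as.vector(lg[, , , 2]), rep(1.5, 16 * 16 * 8))
  # constant model: stride choice cannot change the output
  lg2 <- slidingWindowInfer(m, v, patchSize = c(8, 8, 8),
                            stride = c(4, 4, 8))
  expect_equal(lg2, lg)
  expect_error(slidingWindowInfer(m, v, patchSize = c(8, 8, 8),
                                  stride = c(12, 4, 8)), "stride")
  expect_error(slidingWindowInfer(m, array(0, c(4, 4, 4)),
                                  patchSize = c(8, 8, 8)), "smaller")
})

test_that("overlapping patches average to the per-voxel mean", {
  m <- linModel(cls = 1)
  v <- array(runif(12 * 8 * 8), c(12, 8, 8))
  lg <- slidingWindowInfer(m, v, patchSize = c(8, 8, 8),
                           stride = c(4, 4, 8))
  manual <- array(0, dim(v))
  cnt <- array(0, dim(v))
  for (ox in c(0, 4)) {
    idx <- ox + 1:8
    po <- agnetForward(m, v[idx, , , drop = FALSE])
    manual[idx, , ] <- manual[idx, , ] + po[, , , 1]
    cnt[idx, , ] <- cnt[idx, , ] + 1
  }
  expect_equal(lg[, , , 1], manual / cnt, tolerance = 1e-12)
})

test_that("TTA merging: empty set, constant model, order invariance", {
  m <- constModel(c(0.2, -0.4, 1.1))
  v <- array(runif(16 * 16 * 4), c(16, 16, 4))
  plain <- ttaPredict(m, v, transforms = list(), patchSize = c(16, 16, 4))
  lg <- slidingWindowInfer(m, v, patchSize = c(16, 16, 4))
  expect_equal(plain$logits, lg)

  # spatially constant model: TTA output equals plain output exactly
  full <- ttaPredict(m, v, patchSize = c(16, 16, 4))
  expect_equal(full$logits, plain$logits, tolerance = 1e-12)
  expect_equal(full$labels, plain$labels)

  # per-voxel probabilities sum to one
  ps <- apply(full$probs, 1:3, sum)
  expect_lt(max(abs(ps - 1)), 1e-5)

  # order of transforms does not matter
  mr <- agnetInit(agnetConfig(nScales = 2, baseChannels = 2), seed = 9)
  a <- ttaPredict(mr, v, defaultTTA(), patchSize = c(16, 16, 4))
  b <- ttaPredict(mr, v, rev(defaultTTA()), patchSize = c(16, 16, 4))
  expect_equal(a$probs, b$probs, tolerance = 1e-10)
})

test_that("padded-in voxels are excluded from the TTA average", {
  # identity model on a constant volume: any pad contamination in the
  # merge would pull the class logit below its constant value
  m <- linModel(cls = 2)
  v <- array(1, c(16, 16, 4))
  res <- ttaPredict(m, v, list(ttaTransform("translation", 6)),
                    patchSize = c(16, 16, 4))
  plain <- ttaPredict(m, v, list(), patchSize = c(16, 16, 4))
  expect_equal(res$logits[, , , 2], plain$logits[, , , 2], tolerance = 1e-6)
})

test_that("translation TTA reproduces a convolution's equivariance", {
  k <- matrix(c(0, 1, 0, 1, 2, 1, 0, 1, 0), 3) / 6
  m <- linModel(cls = 2, k1 = k)
  v <- array(runif(24 * 24 * 4), c(24, 24, 4))
  tr <- list(ttaTransform("translation", 5), ttaTransform("translation", 10))
  res <- ttaPredict(m, v, tr, patchSize = c(24, 24, 4))
  plain <- ttaPredict(m, v, list(), patchSize = c(24, 24, 4))
  # pure convolutions commute with translation; compare away from the
  # shift border and the kernel's 1-voxel support
  core <- res$logits[4:12, 3:22, , 2]
  expect_equal(core, plain$logits[4:12, 3:22, , 2], tolerance = 1e-9)
  expect_error(ttaTransform("translation", 2.5), "whole-voxel")
})
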