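# Small label volumes with hand-placed structures; the phantom supplies
# realistic HU volumes for the abdomen mask.

test_that("abdomen mask excludes air, keeps the body, fills holes", {
  sp <- testPhantomSpec(seed = 5)
  ph <- generatePhantom(sp)
  hu <- voxelData(ph$ct)
  cfg <- postprocessConfig()
  mask <- abdomenMask(ph$ct, cfg)
  # no air voxel survives (air is -1000 HU, far below the threshold)
  expect_true(all(hu[mask == 1L] > -500 + 1e-9 - 1e6 * 0))
  air <- hu < -900
  expect_true(all(mask[air] == 0L))
  # with zero erosion the mask is exactly the filled largest component
  cfg0 <- postprocessConfig(erosionRadius = 0)
  m0 <- abdomenMask(ph$ct, cfg0)
  thr <- array(as.integer(hu >= -500), dim(hu))
  lab <- bruteComponents(thr, 26)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  # every kept-component voxel is in the mask (holes may add more)
  expect_true(all(m0[keep] == 1L))
  # erosion shrinks: eroded mask is a subset
  expect_true(all(mask <= m0))
  expect_error(abdomenMask(array(-1000, c(8, 8, 8)), cfg), "degenerate")
})

test_that("two-blob fields keep only the larger blob", {
  pairs <- list(list(c(6, 6, 6), c(15, 15, 15)),
                list(c(5, 14, 7), c(15, 5, 14)),
                list(c(14, 6, 13), c(5, 15, 5)))
  for (pair in pairs) {
    d <- c(20, 20, 20)
    vol <- array(-1000, d)
    c1 <- pair[[1]]; c2 <- pair[[2]]
    g <- expand.grid(x = 1:20, y = 1:20, z = 1:20)
    d1 <- array(sqrt((g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2), d)
    d2 <- array(sqrt((g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2), d)
    vol[d1 <= 4] <- 50
    vol[d2 <= 2.5] <- 50
    m <- abdomenMask(vol, postprocessConfig(erosionRadius = 0))
    lab <- bruteComponents(array(as.integer(vol > -500), d), 26)
    sizes <- tabulate(lab[lab > 0])
    expect_equal(which(m == 1L), which(lab == which.max(sizes)))
  }
})

test_that("out-of-abdomen predictions are zeroed, straddlers trimmed", {
  d <- c(12, 12, 6)
  mask <- array(0L, d); mask[4:9, 4:9, ] <- 1L
  pred <- array(0L, d)
  pred[5:6, 5:6, 2] <- 1L           # pancreas inside
  pred[5, 7, 3] <- 2L               # cyst inside: unchanged
  pred[1, 1, 1] <- 2L               # cyst outside: removed
  pred[8:11, 5, 4] <- 2L            # straddling cyst: outside half zeroed
  r <- filterOutsideAbdomen(pred, mask)
  out <- r$pred
  expect_equal(out[5, 7, 3], 2L)
  expect_equal(out[1, 1, 1], 0L)
  expect_equal(sum(out[8:11, 5, 4] == 2L), 2)  # voxels 8,9 survive
  expect_true(all(out[mask == 0L] == 0L))
  expect_true(all(out <= pred))  # filters only remove
  rep <- r$report
  expect_equal(sum(rep$removed_by == "abdomen"), 1)
  # the prediction fully inside is untouched
  r2 <- filterOutsideAbdomen(r$pred, mask)
  expect_identical(r2$pred, r$pred)
})

test_that("contact filter honours the neighbourhood stencil", {
  d <- c(10, 10, 10)
  pred <- array(0L, d)
  pred[5, 5, 5] <- 1L               # single pancreas voxel
  pred[6, 6, 6] <- 2L               # corner-diagonal cyst
  pred[1:2, 1, 1] <- 2L             # isolated far cyst
  r26 <- filterNoncontactCysts(pred, postprocessConfig(contactConnectivity = 26))
  expect_equal(r26$pred[6, 6, 6], 2L)                # corner contact kept
  expect_true(all(r26$pred[1:2, 1, 1] == 0L))        # isolated removed
  expect_equal(sum(r26$report$removed_by == "contact"), 1)
  r6 <- filterNoncontactCysts(pred, postprocessConfig(contactConnectivity = 6))
  expect_equal(r6$pred[6, 6, 6], 0L)                 # removed under 6-conn
  # face contact survives even under 6-connectivity
  pred2 <- array(0L, d); pred2[5, 5, 5] <- 1L; pred2[6, 5, 5] <- 2L
  expect_equal(filterNoncontactCysts(
    pred2, postprocessConfig(contactConnectivity = 6))$pred[6, 5, 5], 2L)
  # no pancreas predicted: every cyst removed
  pred3 <- array(0L, d); pred3[2:4, 2:4, 2] <- 2L
  expect_true(all(filterNoncontactCysts(pred3,
                                        postprocessConfig())$pred == 0L))
})

test_that("size filter: survival exactly when size >= the minimum", {
  cfg <- postprocessConfig()   # minimum 10 voxels
  for (s in 1:20) {
    pred <- array(0L, c(10, 10, 10))
    # boustrophedon snake over 5-wide rows: always one component
    i <- seq_len(s) - 1L
    y <- i %/% 5L + 1L
    x <- ifelse(y %% 2L == 1L, i %% 5L + 1L, 5L - i %% 5L)
    pred[cbind(x, y, 1L)] <- 2L
    r <- filterSmallComponents(pred, cfg)
    if (s >= 10) expect_equal(sum(r$pred == 2L), s)
    else expect_equal(sum(r$pred == 2L), 0)
  }
  # empty prediction: empty output and report
  r0 <- filterSmallComponents(array(0L, c(5, 5, 5)), cfg)
  expect_true(all(r0$pred == 0L))
  expect_equal(nrow(r0$report), 0)
})

test_that("filters match the flood-fill oracle on random label fields", {
  cfg <- postprocessConfig()
  for (seed in 1:25) {
    pred <- randomLabelVolume(seed)
    d <- dim(pred)
    lab <- bruteComponents(array(as.integer(pred == 2L), d), 26)
    k <- max(lab)
    sizes <- if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer(0)
    touch <- bruteTouches(lab, pred == 1L, 26)
    # contact filter
    rc <- filterNoncontactCysts(pred, cfg)
    expC <- pred
    if (k > 0) expC[lab %in% which(!touch)] <- 0L
    expect_identical(as.vector(rc$pred), as.vector(expC))
    # size filter
    rs <- filterSmallComponents(pred, cfg)
    expS <- pred
    if (k > 0) expS[lab %in% which(sizes < 10)] <- 0L
    expect_identical(as.vector(rs$pred), as.vector(expS))
  }
})

test_that("full pipeline removes one component per reason and is idempotent", {
  sp <- testPhantomSpec(seed = 21, nCysts = 1)
  ph <- generatePhantom(sp)
  truth <- voxelData(ph$labels)
  d <- dim(truth)
  mask <- abdomenMask(ph$ct, postprocessConfig())
  pred <- truth
  # (a) border blob outside the eroded abdomen (in the air corner)
  pred[1:3, 1:3, 1] <- 2L
  # (b) detached cyst inside the abdomen, far from the pancreas
  inside <- which(mask == 1L & truth == 0L, arr.ind = TRUE)
  pan <- which(truth == 1L, arr.ind = TRUE)
  dist2pan <- function(v) min(sqrt(colSums((t(pan) - v)^2)))
  far <- inside[apply(inside, 1, dist2pan) > 6, , drop = FALSE]
  seedVox <- far[which.max(far[, 3]), ]
  blob <- far[abs(far[, 1] - seedVox[1]) <= 1 &
                abs(far[, 2] - seedVox[2]) <= 1 &
                abs(far[, 3] - seedVox[3]) <= 1, , drop = FALSE]
  pred[blob] <- 2L
  # (c) 5-voxel speck touching the pancreas (passes contact, fails size)
  bnd <- which(truth == 1L, arr.ind = TRUE)
  cyst <- which(truth == 2L, arr.ind = TRUE)
  dist2cyst <- apply(bnd, 1, function(v) min(sqrt(colSums((t(cyst) - v)^2))))
  bnd <- bnd[dist2cyst > 8, , drop = FALSE]
  sv <- bnd[which.max(bnd[, 1]), ]
  speck <- rbind(sv + c(1, 0, 0), sv + c(2, 0, 0), sv + c(3, 0, 0),
                 sv + c(1, 1, 0), sv + c(1, 0, 1))
  speck <- speck[speck[, 1] <= d[1] & speck[, 2] <= d[2] &
                   speck[, 3] <= d[3], , drop = FALSE]
  pred[speck] <- 2L

  r <- postprocessPipeline(LabelVolume(pred, voxelSpacing(ph$ct)), ph$ct)
  rep <- r$report
  expect_equal(sum(rep$removed_by == "abdomen"), 1)
  expect_equal(sum(rep$removed_by == "contact"), 1)
  expect_equal(sum(rep$removed_by == "size"), 1)
  expect_equal(sum(rep$removed_by == "none"), 1)
  # the true cyst survives intact
  expect_true(all(r$pred@voxels[truth == 2L] == 2L))
  # survivors are a voxel-wise subset of the input
  expect_true(all(voxelData(r$pred) <= pred))
  # idempotence
  r2 <- postprocessPipeline(r$pred, ph$ct)
  expect_identical(voxelData(r2$pred), voxelData(r$pred))
  expect_true(all(r2$report$removed_by == "none"))
})

test_that("a clean phantom prediction passes untouched", {
  ph <- generatePhantom(testPhantomSpec(seed = 31, nCysts = 2))
  r <- postprocessPipeline(ph$labels, ph$ct)
  expect_identical(voxelData(r$pred), voxelData(ph$labels))
  expect_true(all(r$report$removed_by == "none"))
  expect_equal(nrow(r$report), 2)
})
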