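test_that("dice score matches its formula and edge cases", {
  a <- array(0L, c(4, 4, 2)); b <- array(0L, c(4, 4, 2))
  expect_equal(diceScore(a, b, 2L), 1)            # both empty
  a[1:3, 1, 1] <- 2L                              # |P| = 3
  b[2:3, 1, 1] <- 2L; b[1, 2:4, 1] <- 2L          # |T| = 5, overlap 2
  expect_equal(diceScore(a, b, 2L), 2 * 2 / (3 + 5))
  expect_equal(diceScore(a, a, 2L), 1)
  c2 <- array(0L, c(4, 4, 2)); c2[4, 4, 2] <- 2L  # disjoint, nonempty
  expect_equal(diceScore(a, c2, 2L), 0)
  expect_error(diceScore(a, array(0L, c(2, 2, 2)), 2L), "disagree")
})

test_that("study classification follows the minimal-overlap rule", {
  d <- c(6, 6, 4)
  truth <- array(0L, d); truth[2:4, 2:4, 2] <- 2L; truth[2:4, 5, 2] <- 1L
  # control with empty prediction: TN
  o <- classifyStudy(array(0L, d), NULL, isCase = FALSE)
  expect_equal(o$outcome, "TN")
  expect_false(o$detected)
  # control with any surviving cyst: FP
  fp <- array(0L, d); fp[1, 1, 1] <- 2L
  expect_equal(classifyStudy(fp, NULL, isCase = FALSE)$outcome, "FP")
  # case with a single overlapping voxel: TP
  pr <- array(0L, d); pr[4, 4, 2] <- 2L
  expect_equal(classifyStudy(pr, truth, isCase = TRUE)$outcome, "TP")
  # case with a cyst nowhere overlapping truth: FN (exhaustive check)
  miss <- array(0L, d); miss[6, 6, 4] <- 2L
  expect_equal(sum(miss == 2L & truth == 2L), 0)  # brute intersection
  expect_equal(classifyStudy(miss, truth, isCase = TRUE)$outcome, "FN")
  expect_error(classifyStudy(pr, NULL, isCase = TRUE), "truth")
})

test_that("cohort metrics recover count arithmetic and risk groups", {
  d <- c(4, 4, 2)
  tEmpty <- array(0L, d)
  tCyst <- array(0L, d); tCyst[2, 2, 1] <- 2L
  hit <- tCyst; missP <- array(0L, d)
  mk <- function(pred, truth, case, grp)
    classifyStudy(pred, if (case) truth else NULL, case, riskGroup = grp)
  # 10 cases / 8 detected (5/5 high, 3/5 low), 4 controls / 3 clean
  outcomes <- c(
    lapply(1:5, function(i) mk(hit, tCyst, TRUE, "high")),
    lapply(1:3, function(i) mk(hit, tCyst, TRUE, "low")),
    lapply(1:2, function(i) mk(missP, tCyst, TRUE, "low")),
    lapply(1:3, function(i) mk(tEmpty, NULL, FALSE, "none")),
    list(mk(tCyst, NULL, FALSE, "none")))
  met <- cohortMetrics(outcomes)
  expect_equal(met$sensitivity, 0.8)
  expect_equal(met$specificity, 0.75)
  expect_equal(unname(met$sensitivityByGroup["high"]), 1.0)
  expect_equal(unname(met$sensitivityByGroup["low"]), 0.6)
  expect_equal(unname(met$counts), c(8L, 2L, 1L, 3L))
  # the four counts partition the cohort
  expect_equal(sum(met$counts), length(outcomes))
  # invariance under reordering
  met2 <- cohortMetrics(rev(outcomes))
  expect_equal(met2$sensitivity, met$sensitivity)
  expect_equal(met2$specificity, met$specificity)
  # all-correct cohort
  metAll <- cohortMetrics(list(mk(hit, tCyst, TRUE, "high"),
                               mk(tEmpty, NULL, FALSE, "none")))
  expect_equal(metAll$sensitivity, 1)
  expect_equal(metAll$specificity, 1)
  # undefined metrics reported as NA
  expect_true(is.na(cohortMetrics(list(mk(hit, tCyst, TRUE,
                                          "high")))$specificity))
  expect_error(cohortMetrics(list()), "outcome")
})

test_that("classification agrees with a voxel-set oracle on random fields", {
  for (seed in 1:20) {
    pred <- randomLabelVolume(seed, d = c(10, 10, 10))
    truth <- randomLabelVolume(seed + 1000, d = c(10, 10, 10))
    o <- classifyStudy(pred, truth, isCase = TRUE, riskGroup = "low")
    overlap <- any(which(pred == 2L) %in% which(truth == 2L))
    expect_equal(o$outcome, if (overlap) "TP" else "FN")
  }
})
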