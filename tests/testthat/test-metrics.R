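test_that("overlap coefficients match exhaustive pixel counts", {
  base <- matrix(FALSE, 4, 4)
  A <- base; A[1, 1:4] <- TRUE                 # |A| = 4
  G <- base; G[1, 3:4] <- TRUE; G[2, 1:2] <- TRUE   # |G| = 4, overlap 2
  expect_equal(diceCoefficient(A, G), 0.5)
  expect_equal(simpsonCoefficient(A, G), 0.5)
  expect_equal(iouCoefficient(A, G), 2 / 6)
  expect_equal(diceCoefficient(A, A), 1)
  expect_equal(simpsonCoefficient(A, A), 1)
  expect_equal(iouCoefficient(A, A), 1)
  D <- base; D[4, 1:2] <- TRUE                 # disjoint from A
  expect_equal(diceCoefficient(A, D), 0)
  expect_equal(iouCoefficient(A, D), 0)
  # subset: Simpson saturates at 1
  S <- base; S[1, 2:4] <- TRUE
  expect_equal(simpsonCoefficient(S, A), 1)
  # undefined sentinels
  expect_true(is.na(diceCoefficient(base, base)))
  expect_true(is.na(simpsonCoefficient(base, A)))
  expect_true(is.na(iouCoefficient(base, base)))
})

test_that("dice, Simpson and IoU satisfy their algebraic relations", {
  set.seed(50)
  for (k in 1:300) {
    A <- randomMask(); G <- randomMask()
    d <- diceCoefficient(A, G); i <- iouCoefficient(A, G)
    s <- simpsonCoefficient(A, G)
    if (!is.na(d) && !is.na(i))
      expect_equal(d, 2 * i / (1 + i), tolerance = 1e-12)
    if (!is.na(d) && !is.na(s) && !is.na(i)) {
      expect_gte(s, d - 1e-15)
      expect_gte(d, i - 1e-15)
    }
    # symmetry in (A, G)
    expect_equal(diceCoefficient(G, A), d)
    expect_equal(simpsonCoefficient(G, A), s)
    expect_equal(iouCoefficient(G, A), i)
  }
})

test_that("Hausdorff distance matches hand-derived cases", {
  a <- matrix(FALSE, 5, 5); a[1, 1] <- TRUE
  b <- matrix(FALSE, 5, 5); b[4, 5] <- TRUE           # offset (3, 4)
  expect_equal(hausdorffDistance(a, b), 5)
  expect_equal(hausdorffDistance(a, a), 0)
  # concentric filled squares, 10x10 inside 14x14, corners offset (2, 2)
  inner <- matrix(FALSE, 20, 20); inner[3:12, 3:12] <- TRUE
  outer_ <- matrix(FALSE, 20, 20); outer_[1:14, 1:14] <- TRUE
  expect_equal(hausdorffDistance(inner, outer_), 2 * sqrt(2))
  expect_true(is.na(hausdorffDistance(a, matrix(FALSE, 5, 5))))
})

test_that("Hausdorff agrees with the brute-force contour oracle", {
  set.seed(51)
  for (k in 1:200) {
    H <- sample(3:12, 1); W <- sample(3:12, 1)
    A <- randomMask(H, W, runif(1, 0.2, 0.7))
    B <- randomMask(H, W, runif(1, 0.2, 0.7))
    expect_equal(hausdorffDistance(A, B), bruteHausdorff(A, B),
                 info = sprintf("case %d", k))
  }
})

test_that("eye-centre distance uses the unrounded centroid", {
  m <- matrix(FALSE, 512, 640)
  m[oculocascade:::.rasterDisk(512, 640, 256, 320, 30)] <- TRUE
  expect_equal(centerDistance(m, c(256, 320)), 0)
  expect_equal(centerDistance(m, c(253, 320)), 3)
  expect_true(is.na(centerDistance(matrix(FALSE, 4, 4), c(1, 1))))
})

test_that("summaries use linear-interpolation quantiles and count failures", {
  rec <- data.frame(structure = "iris", dice = c(0.9, 0.94, 0.98))
  s <- summarizeEvalRecords(rec, metrics = "dice")
  expect_equal(s$median, 0.94)
  expect_equal(s$p25, quantile(c(0.9, 0.94, 0.98), 0.25, names = FALSE))
  one <- summarizeEvalRecords(data.frame(structure = "pupil", dice = 0.7),
                              metrics = "dice")
  expect_equal(unlist(one[, c("median", "p25", "p75")], use.names = FALSE),
               rep(0.7, 3))
  mix <- summarizeEvalRecords(
    data.frame(structure = "iris", dice = c(0.8, NA, 0.9, NA)),
    metrics = "dice")
  expect_equal(mix$n, 2)
  expect_equal(mix$n_undefined, 2)
  expect_equal(mix$median, 0.85)
  expect_error(summarizeEvalRecords(
    data.frame(structure = "iris", dice = NA_real_), metrics = "dice"),
    "undefined")
})

test_that("the dice median is the monotone image of the IoU median", {
  set.seed(52)
  ious <- runif(31, 0.5, 1)
  dices <- 2 * ious / (1 + ious)
  expect_equal(median(dices), 2 * median(ious) / (1 + median(ious)),
               tolerance = 1e-12)
  # the published iris/pupil medians are consistent with this identity
  expect_equal(round(2 * 0.88 / 1.88, 2), 0.94)
  expect_equal(round(2 * 0.94 / 1.94, 2), 0.97)
})
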