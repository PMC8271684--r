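test_that("binarisation uses a strict threshold", {
  expect_true(all(binarizeMap(matrix(0.3, 4, 4), 0.2)))
  expect_false(any(binarizeMap(matrix(0.2, 4, 4), 0.2)))
  expect_equal(as.vector(binarizeMap(matrix(c(0.1, 0.16, 0.5), 1), 0.15)),
               c(FALSE, TRUE, TRUE))
  expect_error(binarizeMap(matrix(c(0.5, 1.2), 1), 0.5), "\\[0, 1\\]")
  # lowering the threshold never shrinks the mask (pointwise superset)
  p <- matrix(runif(100), 10, 10)
  lo <- binarizeMap(p, 0.15); hi <- binarizeMap(p, 0.5)
  expect_true(all(lo | !hi))
})

test_that("post-processing keeps the largest component and fills holes", {
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:3] <- TRUE                      # 10 px component
  m[25, 25:27] <- TRUE                     # 3 px component, far away
  out <- postprocessMask(m, closingRadius = 1)
  expect_true(all(out[2:6, 2:3]))
  expect_false(any(out[20:30, 20:30]))
  # one-pixel interior hole is closed
  h <- matrix(FALSE, 9, 9); h[3:7, 3:7] <- TRUE; h[5, 5] <- FALSE
  expect_true(postprocessMask(h, closingRadius = 1)[5, 5])
  # all-zero stays all-zero
  expect_equal(sum(postprocessMask(matrix(FALSE, 8, 8), 1)), 0)
  # diagonal adjacency joins components (8-connectivity)
  d <- matrix(FALSE, 10, 10); d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[8, 8] <- TRUE
  out_d <- postprocessMask(d, closingRadius = 0)
  expect_equal(sum(out_d), 2)
  # equal-size tie goes to the lexicographically smallest (row, col)
  t2 <- matrix(FALSE, 12, 12)
  t2[7:8, 2:3] <- TRUE                     # min row 6 (0-based)
  t2[2:3, 7:8] <- TRUE                     # min row 1 -> wins
  out_t <- postprocessMask(t2, closingRadius = 0)
  expect_true(all(out_t[2:3, 7:8]))
  expect_false(any(out_t[7:8, 2:3]))
})

test_that("centroids are rounded half-up", {
  m <- matrix(FALSE, 10, 12); m[6, 10] <- TRUE
  expect_equal(maskCentroid(m), c(5, 9))
  sq <- matrix(FALSE, 10, 10); sq[1:4, 1:4] <- TRUE   # rows/cols 0..3
  expect_equal(maskCentroid(sq), c(2, 2))
  expect_equal(maskCentroid(sq, rounded = FALSE), c(1.5, 1.5))
  expect_error(maskCentroid(matrix(FALSE, 3, 3)), "no foreground")
})

test_that("window clamping translates minimally into the frame", {
  b <- clampWindow(c(256, 320), 350, c(512, 640))
  expect_equal(c(b@rowStart, b@rowStop, b@colStart, b@colStop),
               c(81, 431, 145, 495))
  expect_false(b@translated)
  b2 <- clampWindow(c(10, 320), 350, c(512, 640))
  expect_equal(c(b2@rowStart, b2@rowStop), c(0, 350))
  expect_true(b2@translated)
  b3 <- clampWindow(c(511, 639), 350, c(512, 640))
  expect_equal(c(b3@rowStart, b3@rowStop, b3@colStart, b3@colStop),
               c(162, 512, 290, 640))
  expect_error(clampWindow(c(5, 5), 350, c(300, 640)), "larger than")
})

test_that("ROI extraction and paste-back are exact inverses", {
  box <- WindowBox(81, 431, 145, 495)
  fr <- matrix(7, 512, 640)
  expect_true(all(extractRoi(fr, box) == 7))
  fr[82, 146] <- 99                        # 0-based (81, 145)
  crop <- extractRoi(fr, box)
  expect_equal(crop[1, 1], 99)
  expect_equal(dim(crop), c(350L, 350L))
  m <- matrix(runif(512 * 640) > 0.5, 512, 640)
  expect_identical(pasteBack(extractRoi(m, box), box, c(512, 640)),
                   {z <- matrix(FALSE, 512, 640)
                    z[82:431, 146:495] <- m[82:431, 146:495]; z})
  roi0 <- matrix(FALSE, 350, 350)
  expect_equal(sum(pasteBack(roi0, box, c(512, 640))), 0)
  roi1 <- matrix(FALSE, 350, 350); roi1[1, 1] <- TRUE
  expect_true(pasteBack(roi1, box, c(512, 640))[82, 146])
  expect_error(pasteBack(matrix(FALSE, 10, 10), box, c(512, 640)), "box is")
  expect_error(extractRoi(matrix(0, 300, 300), box), "clamp")
})

test_that("nearest-neighbour mask resizing round-trips block-constant masks", {
  set.seed(40)
  for (k in 1:10) {
    coarse <- matrix(runif(16 * 16) > 0.5, 16, 16)
    up <- resizeMaskNearest(coarse, c(64, 64))
    down <- resizeMaskNearest(up, c(16, 16))
    expect_identical(down, coarse)
    # and the up-scaled mask is idempotent under another round trip
    expect_identical(resizeMaskNearest(resizeMaskNearest(up, c(16, 16)),
                                       c(64, 64)), up)
  }
})

test_that("oracle models drive the cascade back to ground truth", {
  sc <- samplePhantomScene(cleanPhantomSpec(irisR = 120, pupilFrac = 0.45),
                           seed = 5)
  res <- runCascade(frameImage(sc), oracleModels(sc))
  expect_gte(diceCoefficient(irisMask(res), irisMask(sc)), 0.98)
  expect_gte(diceCoefficient(pupilMask(res), pupilMask(sc)), 0.98)
  expect_length(resultFlags(res), 0)
  # predicted masks never leave the window footprint
  b <- roiBox(res)
  outside <- matrix(TRUE, 512, 640)
  outside[(b@rowStart + 1):b@rowStop, (b@colStart + 1):b@colStop] <- FALSE
  expect_false(any(irisMask(res) & outside))
  expect_false(any(pupilMask(res) & outside))
})

test_that("an empty localisation map falls back to a centred window", {
  sc <- samplePhantomScene(cleanPhantomSpec(), seed = 6)
  models <- oracleModels(sc)
  models$roi <- function(image) image * 0
  res <- runCascade(frameImage(sc), models)
  expect_true("roi_empty" %in% resultFlags(res))
  expect_equal(eyeCenter(res), c(256, 320))
  b <- roiBox(res)
  expect_equal(c(b@rowStart, b@colStart), c(81, 145))
})

test_that("an eye at the frame border translates the window", {
  spec <- cleanPhantomSpec(irisR = 120, pupilFrac = 0.4)
  spec@centerJitter <- 0
  sc <- samplePhantomScene(spec, seed = 7)
  # shift the scene's geometry to the top edge by rebuilding the masks
  iris <- oculocascade:::.rasterDisk(512, 640, 60, 320, 120)
  pupil <- oculocascade:::.rasterDisk(512, 640, 60, 320, 48)
  img <- matrix(210, 512, 640); img[iris] <- 110; img[pupil] <- 30
  sc@image <- img; sc@irisMask <- iris; sc@pupilMask <- pupil
  sc@eyeCenter <- maskCentroid(iris)
  sc@roiBox <- deriveRoiBox(iris)
  res <- runCascade(img, oracleModels(sc))
  expect_true("window_translated" %in% resultFlags(res))
  b <- roiBox(res)
  expect_true(b@rowStart >= 0 && b@rowStop <= 512)
  expect_gte(diceCoefficient(irisMask(res), iris), 0.98)
})

test_that("a frozen ROI box skips localisation", {
  sc <- samplePhantomScene(cleanPhantomSpec(), seed = 8)
  res <- runCascade(frameImage(sc), oracleModels(sc), roiBox = roiBox(sc))
  expect_gte(diceCoefficient(irisMask(res), irisMask(sc)), 0.98)
})
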