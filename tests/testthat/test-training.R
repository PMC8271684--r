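test_that("localisation targets are the merged iris-and-pupil mask", {
  H <- 64L; W <- 80L
  iris <- matrix(FALSE, H, W); iris[20:40, 30:50] <- TRUE
  pupil <- matrix(FALSE, H, W); pupil[25:35, 35:45] <- TRUE  # subset
  img <- matrix(runif(H * W, 0, 255), H, W)
  pr <- prepareRoiPairs(list(img), list(iris), list(pupil), size = c(H, W))
  expect_equal(pr$masks[, , 1] == 1, iris)     # union equals the iris disk
  # disjoint masks: merged foreground is the sum of the two areas
  p2 <- matrix(FALSE, H, W); p2[50:55, 5:10] <- TRUE
  pr2 <- prepareRoiPairs(list(img), list(iris), list(p2), size = c(H, W))
  expect_equal(sum(pr2$masks[, , 1]), sum(iris) + sum(p2))
  expect_error(prepareRoiPairs(list(img), list(iris[1:10, ]), list(pupil)),
               "different shapes")
})

test_that("full frames come out at the network input size", {
  sc <- samplePhantomScene(cleanPhantomSpec(), seed = 1)
  pr <- prepareRoiPairs(list(frameImage(sc)), list(irisMask(sc)),
                        list(pupilMask(sc)), size = c(256L, 256L))
  expect_equal(dim(pr$images), c(256L, 256L, 1L))
  expect_true(all(pr$images >= 0 & pr$images <= 1))
  expect_true(all(pr$masks %in% c(0, 1)))
})

test_that("crop pairs respect the window geometry", {
  sc <- samplePhantomScene(cleanPhantomSpec(), seed = 1)
  cp <- prepareCropPairs(list(frameImage(sc)), list(irisMask(sc)),
                         list(roiBox(sc)), size = c(256L, 256L))
  expect_equal(dim(cp$images), c(256L, 256L, 1L))
  # an empty mask inside the box is legal and kept as an all-zero target
  empty <- matrix(FALSE, 512, 640)
  cp0 <- prepareCropPairs(list(frameImage(sc)), list(empty),
                          list(roiBox(sc)), size = c(64L, 64L))
  expect_equal(sum(cp0$masks), 0)
  # a box reaching outside the frame is the caller's error
  small <- matrix(0, 300, 640)
  expect_error(prepareCropPairs(list(small), list(small > 1),
                                list(WindowBox(0, 350, 0, 350))),
               "clamp")
})

test_that("the identity transform reproduces the pair exactly", {
  img <- matrix(as.numeric(1:48), 6, 8)
  msk <- matrix(FALSE, 6, 8); msk[2:4, 3:6] <- TRUE
  tr <- list(flipH = FALSE, flipV = FALSE, angle = 0, ty = 0, tx = 0,
             zoom = 1)
  out <- augmentPair(img, msk, transform = tr)
  expect_equal(out$image, img)
  expect_identical(out$mask, msk)
})

test_that("a 180-degree rotation moves a corner pixel to the opposite corner", {
  m <- matrix(FALSE, 9, 7); m[1, 1] <- TRUE
  tr <- list(flipH = FALSE, flipV = FALSE, angle = 180, ty = 0, tx = 0,
             zoom = 1)
  out <- augmentPair(m * 5, m, transform = tr)
  expect_identical(which(out$mask), which(matrix(FALSE, 9, 7) | {
    z <- matrix(FALSE, 9, 7); z[9, 7] <- TRUE; z
  }))
})

test_that("translation shifts the mask centroid by the requested pixels", {
  m <- matrix(FALSE, 201, 201)
  m[oculocascade:::.rasterDisk(201, 201, 60, 100, 12)] <- TRUE
  tr <- list(flipH = FALSE, flipV = FALSE, angle = 0, ty = 70, tx = 0,
             zoom = 1)
  out <- augmentPair(m * 1, m, transform = tr)
  expect_equal(maskCentroid(out$mask, rounded = FALSE)[1],
               maskCentroid(m, rounded = FALSE)[1] + 70)
  expect_equal(maskCentroid(out$mask, rounded = FALSE)[2],
               maskCentroid(m, rounded = FALSE)[2])
})

test_that("masks stay binary and sampling is seed-reproducible", {
  set.seed(20)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  msk <- oculocascade:::.rasterDisk(64, 64, 30, 30, 15)
  for (k in 1:15) {
    out <- augmentPair(img, msk)
    expect_true(is.logical(out$mask))
    expect_true(abs(out$transform$tx) <= 70 && abs(out$transform$ty) <= 70)
    expect_true(out$transform$zoom >= 0.8 && out$transform$zoom <= 1.2)
  }
  set.seed(7); a <- augmentPair(img, msk)
  set.seed(7); b <- augmentPair(img, msk)
  expect_identical(a, b)
})

test_that("steps per epoch use ceiling division", {
  expect_identical(stepsPerEpoch(650, 4), 163L)
  expect_identical(stepsPerEpoch(8, 4), 2L)
  expect_identical(stepsPerEpoch(9, 4), 3L)
})

test_that("training history, checkpointing and error handling behave", {
  set.seed(30)
  n <- 8; H <- 32
  imgs <- array(0, c(H, H, n)); msks <- array(0, c(H, H, n))
  for (i in 1:n) {
    m <- oculocascade:::.rasterDisk(H, H, runif(1, 12, 20), runif(1, 12, 20),
                                    runif(1, 5, 9))
    msks[, , i] <- m
    imgs[, , i] <- 0.1 + 0.8 * m
  }
  model <- buildUnet(UNetSpec(baseFilters = 4L, depth = 3L, inputSize = H),
                     seed = 1)
  cfg <- TrainConfig(epochs = 6L, batchSize = 4L, learningRate = 1e-3,
                     seed = 2)
  expect_message(fit <- trainNetwork(model, list(images = imgs, masks = msks),
                                     cfg), "validation")
  expect_equal(nrow(fit@history), 6L)
  expect_equal(attr(fit@history, "steps_per_epoch"), stepsPerEpoch(n, 4))
  # noiseless separable toy: loss decreases with at most one stall
  expect_lte(sum(diff(fit@history$loss) >= 0), 1)
  # the checkpoint rule returns the epoch with minimum training loss
  expect_equal(fit@bestEpoch, which.min(fit@history$loss))
  expect_error(suppressMessages(trainNetwork(model, list(images = imgs[, , 0],
                                                         masks = msks[, , 0]))),
               "empty dataset")
  expect_error(suppressMessages(
    trainNetwork(model, list(images = imgs[1:16, , ], masks = msks[1:16, , ]))),
    "expects")
})

test_that("two seeded runs produce identical histories and weights", {
  set.seed(31)
  n <- 6; H <- 16
  imgs <- array(runif(H * H * n), c(H, H, n))
  msks <- array(as.numeric(runif(H * H * n) > 0.6), c(H, H, n))
  run <- function() {
    m <- buildUnet(UNetSpec(baseFilters = 2L, depth = 2L, inputSize = H),
                   seed = 9)
    suppressMessages(trainNetwork(m, list(images = imgs, masks = msks),
                                  TrainConfig(epochs = 3L, seed = 13),
                                  AugmentationSpec(translateMax = 4)))
  }
  a <- run(); b <- run()
  expect_identical(a@history, b@history)
  expect_identical(a@weights, b@weights)
})
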