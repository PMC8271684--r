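test_that("disk rasterisation matches the brute-force lattice count", {
  sc <- samplePhantomScene(cleanPhantomSpec(irisR = 100, pupilFrac = 0.4),
                           seed = 2)
  expect_equal(sum(irisMask(sc)),
               bruteDiskCount(512, 640, 256, 320, 100))
  expect_equal(sum(pupilMask(sc)),
               bruteDiskCount(512, 640, 256, 320, 40))
  # quantisation stays near the analytic areas
  expect_lt(abs(sum(irisMask(sc)) - pi * 100^2), 150)
  expect_lt(abs(sum(pupilMask(sc)) - pi * 40^2), 60)
  expect_equal(eyeCenter(sc), c(256, 320))
})

test_that("a pupil as large as the iris is rejected", {
  expect_error(PhantomSpec(pupilFractionRange = c(0.5, 1.0)),
               "strictly")
  expect_error(PhantomSpec(irisRadiusRange = c(140, 90)), "interval")
})

test_that("scenes are bit-identical under a fixed seed", {
  s1 <- samplePhantomScene(PhantomSpec(), seed = 11)
  s2 <- samplePhantomScene(PhantomSpec(), seed = 11)
  expect_identical(frameImage(s1), frameImage(s2))
  expect_identical(irisMask(s1), irisMask(s2))
  expect_identical(pupilMask(s1), pupilMask(s2))
  expect_identical(s1@params, s2@params)
})

test_that("scene invariants hold across random scenes", {
  set.seed(101)
  orderings <- logical(30)
  for (k in 1:30) {
    sc <- samplePhantomScene(PhantomSpec())
    expect_true(all(!pupilMask(sc) | irisMask(sc)))   # pupil subset of iris
    b <- roiBox(sc)
    expect_true(b@rowStart >= 0 && b@rowStop <= 512 &&
                b@colStart >= 0 && b@colStop <= 640)
    # the 350 px window holds the whole iris whenever the iris fits
    ir <- which(irisMask(sc), arr.ind = TRUE) - 1L
    if (diff(range(ir[, 1])) < 350 && diff(range(ir[, 2])) < 350) {
      inside <- ir[, 1] >= b@rowStart & ir[, 1] < b@rowStop &
                ir[, 2] >= b@colStart & ir[, 2] < b@colStop
      expect_true(all(inside))
    }
    img <- frameImage(sc)
    ring <- irisMask(sc) & !pupilMask(sc)
    sclera <- !irisMask(sc)
    orderings[k] <- mean(img[pupilMask(sc)]) < mean(img[ring]) &&
                    mean(img[ring]) < mean(img[sclera])
  }
  expect_gte(mean(orderings), 0.99)
})

test_that("deriveRoiBox centres and clamps as specified", {
  m <- matrix(FALSE, 512, 640)
  m[250:262 + 1, 314:326 + 1] <- TRUE          # centroid (256, 320)
  b <- deriveRoiBox(m, 350)
  expect_equal(c(b@rowStart, b@rowStop, b@colStart, b@colStop),
               c(81, 431, 145, 495))
  m2 <- matrix(FALSE, 512, 640)
  m2[9:13, 319:323] <- TRUE                    # centroid near the top edge
  b2 <- deriveRoiBox(m2, 350)
  expect_equal(c(b2@rowStart, b2@rowStop), c(0, 350))
  expect_equal(c(b2@colStart, b2@colStop), c(145, 495))
  expect_true(b2@translated)
  expect_error(deriveRoiBox(matrix(FALSE, 512, 640)), "no foreground")
})

test_that("dataset writing produces triplets and a reproducible manifest", {
  spec <- PhantomSpec(imageHeight = 96L, imageWidth = 128L,
                      irisRadiusRange = c(20, 30), centerJitter = 10)
  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  man1 <- makePhantomDataset(spec, 5, d1, seed = 3)
  man2 <- makePhantomDataset(spec, 5, d2, seed = 3)
  expect_equal(nrow(man1), 5)
  expect_length(list.files(d1, pattern = "\\.png$"), 15)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # mask PNG round trip is exact
  m <- readMaskPng(file.path(d1, man1$iris_mask[1]))
  sc <- samplePhantomScene(spec, seed = 3, roiWindow = 96L)
  expect_identical(m, irisMask(sc))
  expect_error(makePhantomDataset(spec, 0, tempdir()), ">= 1")
  unlink(c(d1, d2), recursive = TRUE)
})
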