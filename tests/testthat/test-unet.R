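test_that("parameter counts equal the closed-form layer summation", {
  for (base in c(1L, 2L, 4L)) for (depth in c(2L, 3L))
    for (dec in c("upconv_concat", "upsample_concat"))
      for (bn in c(TRUE, FALSE)) {
        spec <- UNetSpec(baseFilters = base, depth = depth,
                         inputSize = 16L, batchNorm = bn, decoderMode = dec)
        expect_equal(countTrainableParams(spec, includeNormStats = FALSE),
                     oracleParamCount(base, depth, bn = bn, decoder = dec),
                     info = sprintf("base %d depth %d %s bn %s",
                                    base, depth, dec, bn))
        expect_equal(countTrainableParams(spec, includeNormStats = TRUE),
                     oracleParamCount(base, depth, bn = bn, decoder = dec) +
                       oracleStatCount(base, depth, bn = bn, decoder = dec))
        # the builder's layer table agrees with both routes
        tab <- unetLayerTable(spec)
        expect_equal(sum(tab$params),
                     countTrainableParams(spec, includeNormStats = FALSE))
      }
})

test_that("the toy architecture matches a hand-summed count", {
  # base 1, depth 2, no batch norm, upsampling decoder:
  # enc 3x3 (1->1) 10 + (1->1) 10; bottleneck (1->2) 20 + (2->2) 38;
  # decoder concat 2+1=3 channels: (3->1) 28 + (1->1) 10; head 1x1 2
  spec <- UNetSpec(baseFilters = 1L, depth = 2L, inputSize = 8L,
                   batchNorm = FALSE, decoderMode = "upsample_concat")
  expect_identical(countTrainableParams(spec), 118L)
})

test_that("doubling the base filters roughly quadruples the parameters", {
  n16 <- countTrainableParams(UNetSpec(baseFilters = 16L),
                              includeNormStats = FALSE)
  n32 <- countTrainableParams(UNetSpec(baseFilters = 32L),
                              includeNormStats = FALSE)
  expect_gt(n32 / n16, 3.5)
  expect_lt(n32 / n16, 4.1)
})

test_that("output shape equals input shape and values stay in (0, 1)", {
  for (dec in c("upconv_concat", "upsample_concat")) {
    spec <- UNetSpec(baseFilters = 2L, depth = 3L, inputSize = c(16L, 24L),
                     decoderMode = dec)
    m <- buildUnet(spec, seed = 4)
    for (img in list(matrix(0, 16, 24), matrix(runif(16 * 24), 16, 24),
                     matrix(1, 16, 24))) {
      p <- predictMap(m, img)
      expect_equal(dim(p), c(16L, 24L))
      expect_true(all(is.finite(p)) && all(p > 0) && all(p < 1))
    }
  }
})

test_that("an input size not divisible by the pooling factor is rejected", {
  expect_error(UNetSpec(inputSize = 250L), "divisible")
  m <- buildUnet(UNetSpec(baseFilters = 2L, depth = 2L, inputSize = 8L))
  expect_error(predictMap(m, matrix(0, 9, 8)), "expects")
})

test_that("backpropagation matches directional finite differences", {
  set.seed(5)
  spec <- UNetSpec(baseFilters = 2L, depth = 3L, inputSize = 16L)
  m <- buildUnet(spec, seed = 7)
  sl <- oculocascade:::.specList(spec)
  x <- runif(16 * 16 * 2)
  y <- as.numeric(runif(16 * 16 * 2) > 0.5)
  lg <- oculocascade:::cpp_unet_lossgrad(m@weights, m@stats, sl, x, y, 2L)
  errs <- vapply(1:5, function(r) {
    d <- rnorm(length(m@weights)); d <- d / sqrt(sum(d^2))
    h <- 2e-3
    fp <- oculocascade:::cpp_unet_lossgrad(m@weights + h * d, m@stats, sl,
                                           x, y, 2L)$loss
    fm <- oculocascade:::cpp_unet_lossgrad(m@weights - h * d, m@stats, sl,
                                           x, y, 2L)$loss
    num <- (fp - fm) / (2 * h)
    abs(num - sum(lg$grad * d)) / max(abs(num), abs(sum(lg$grad * d)))
  }, numeric(1))
  # float arithmetic plus max-pool/ReLU kinks bound the attainable accuracy
  expect_lt(median(errs), 0.02)
})

test_that("filter-configuration comparison returns one curve per base", {
  set.seed(6)
  n <- 6; H <- 16
  imgs <- array(runif(H * H * n), c(H, H, n))
  msks <- array(0, c(H, H, n))
  msks[5:10, 5:10, ] <- 1
  curves <- compareFilterConfigs(c(1L, 2L), list(images = imgs, masks = msks),
                                 epochs = 2L,
                                 spec = UNetSpec(baseFilters = 1L, depth = 2L,
                                                 inputSize = H),
                                 seed = 1)
  expect_equal(nrow(curves), 4L)            # 2 bases x 2 epochs
  expect_setequal(unique(curves$base), c(1, 2))
  expect_true(all(is.finite(curves$loss)))
  expect_error(compareFilterConfigs(integer(), list(images = imgs, masks = msks)),
               "at least one")
})
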