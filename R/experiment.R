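## End-to-end scaled-down study on phantoms: generate a training and a
## held-out set, train the three networks with the standard recipe at
## reduced resolution, run the cascade on the held-out frames and score
## full-frame masks. One function so that scripts and tests exercise the
## identical procedure.

#' Run the scaled-down phantom study
#'
#' Generates \code{nTrain} training and \code{nTest} held-out phantom
#' frames under the default [PhantomSpec()] conditions, trains the
#' eye-localisation, iris and pupil networks (Adam 1e-4, batch 4, binary
#' cross-entropy, best-weights-by-training-loss, full paired augmentation
#' with the translation bound scaled to the network input), runs the
#' cascade on the held-out frames and returns per-frame records plus the
#' median/quartile summary in full-frame coordinates.
#'
#' @param seed integer; fully determines phantom sampling, weight
#'   initialisation, shuffling and augmentation.
#' @param nTrain,nTest training and held-out set sizes.
#' @param netInput network input side (pixels).
#' @param baseFilters,depth architecture scale of all three networks.
#' @param epochs training epochs per network.
#' @param verbose print training progress.
#' @return list with \code{records} (per-frame metrics), \code{summary}
#'   (from [summarizeEvalRecords()]), \code{models}, \code{history} and the
#'   settings used.
#' @export
runScaledExperiment <- function(seed = 1L, nTrain = 300L, nTest = 60L,
                                netInput = 128L, baseFilters = 8L,
                                depth = 5L, epochs = 12L, verbose = FALSE) {
  .withSeed(seed, {
    pspec <- PhantomSpec()
    sz <- c(netInput, netInput)
    nspec <- UNetSpec(baseFilters = baseFilters, depth = depth,
                      inputSize = sz)
    aug <- AugmentationSpec(translateMax = round(70 * netInput / 256))
    tc <- TrainConfig(epochs = epochs, verbose = verbose)
    cfg <- CascadeConfig(netInput = netInput)

    mk <- function() array(0, c(sz, nTrain))
    roiI <- mk(); roiM <- mk(); irisI <- mk(); irisM <- mk()
    pupI <- mk(); pupM <- mk()
    for (i in seq_len(nTrain)) {
      sc <- samplePhantomScene(pspec)
      # same preparation as prepareRoiPairs()/prepareCropPairs(), with the
      # crop-image resize shared between the two fine networks
      roiI[, , i] <- resizeImageBilinear(sc@image, sz) / 255
      roiM[, , i] <- resizeMaskNearest(sc@irisMask | sc@pupilMask, sz)
      ci <- resizeImageBilinear(extractRoi(sc@image, sc@roiBox), sz) / 255
      irisI[, , i] <- ci
      pupI[, , i] <- ci
      irisM[, , i] <- resizeMaskNearest(extractRoi(sc@irisMask * 1,
                                                   sc@roiBox), sz)
      pupM[, , i] <- resizeMaskNearest(extractRoi(sc@pupilMask * 1,
                                                  sc@roiBox), sz)
    }
    test <- lapply(seq_len(nTest), function(i) samplePhantomScene(pspec))

    fit1 <- function(imgs, msks) {
      model <- buildUnet(nspec)
      suppressMessages(trainNetwork(model, list(images = imgs, masks = msks),
                                    tc, aug))
    }
    models <- list(roi = fit1(roiI, roiM), iris = fit1(irisI, irisM),
                   pupil = fit1(pupI, pupM))

    results <- lapply(test, function(sc) runCascade(sc@image, models, cfg))
    records <- evaluateCascade(results, test)
    list(records = records,
         summary = summarizeEvalRecords(records),
         models = models,
         history = lapply(models, function(m) m@history),
         settings = list(seed = seed, nTrain = nTrain, nTest = nTest,
                         netInput = netInput, baseFilters = baseFilters,
                         depth = depth, epochs = epochs))
  })
}

#' Median of one metric from experiment records
#'
#' @param records records from [runScaledExperiment()].
#' @param structure `"iris"` or `"pupil"`.
#' @param metric column name.
#' @return the median over defined records.
#' @export
medianMetric <- function(records, structure, metric) {
  v <- records[[metric]][records$structure == structure]
  median(v[!is.na(v)])
}
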