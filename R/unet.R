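## U-Net construction and parameter accounting. The architecture is the
## classic encoder-decoder: per resolution level two 3x3 "same"
## convolutions, each followed by batch normalisation and a leaky-ReLU, with
## 2x2 max-pooling between encoder levels; feature maps double per encoder
## level and halve per decoder level. The decoder doubles the grid either
## with a parameter-free nearest-neighbour up-sampling ("upsample_concat")
## or a 2x2 up-convolution that halves the feature maps ("upconv_concat",
## the default), then concatenates the encoder skip at the same level. The
## head is a single 1x1 convolution with a sigmoid, so the output is a
## probability map the size of the input.

# flatten a UNetSpec into the list the C++ engine expects
.specList <- function(spec) {
  list(base = spec@baseFilters, depth = spec@depth,
       inch = spec@inputChannels, H = spec@inputSize[1],
       W = spec@inputSize[2], bn = spec@batchNorm,
       slope = spec@leakySlope, decoder = spec@decoderMode)
}

#' Build a U-Net
#'
#' Allocates and initialises all network parameters for the given
#' architecture: He-normal convolution kernels, zero biases, unit/zero
#' batch-norm scale and shift. The sigmoid head's bias starts at the logit
#' of a 10\% foreground prior, so an untrained network under-segments
#' rather than emitting p = 0.5 everywhere - a standard stabilisation for
#' class-imbalanced segmentation. The returned model is untrained; see
#' [trainNetwork()].
#'
#' @param spec a [UNetSpec-class].
#' @param seed optional integer seed for the weight initialisation (the
#'   caller's RNG state is restored afterwards).
#' @return a [UNetModel-class].
#' @examples
#' m <- buildUnet(UNetSpec(baseFilters = 2, depth = 3, inputSize = 32), seed = 1)
#' countTrainableParams(m, includeNormStats = FALSE)
#' @export
buildUnet <- function(spec, seed = NULL) {
  stopifnot(is(spec, "UNetSpec"))
  validObject(spec)
  init <- .withSeed(seed, cpp_unet_init(.specList(spec)))
  new("UNetModel", spec = spec, weights = init$weights, stats = init$stats,
      history = data.frame(), bestEpoch = 0L)
}

#' Count network parameters
#'
#' Returns the number of parameters of a built model (or of the model a
#' [UNetSpec-class] describes). By default the count follows the summary
#' convention under which the reference architecture's published size was
#' quoted: the batch-norm moving mean and variance are included alongside
#' the optimised scalars. Set \code{includeNormStats = FALSE} to count
#' strictly the scalars touched by the optimiser.
#'
#' For the reference architecture (base 16 filters, depth 5, 256 x 256
#' single-channel input, up-convolution decoder) this returns 1,947,665
#' (1,944,241 optimised scalars plus 3,424 moving statistics).
#'
#' @param x a [UNetSpec-class] or [UNetModel-class].
#' @param includeNormStats include batch-norm moving statistics
#'   (default TRUE).
#' @return integer parameter count.
#' @export
countTrainableParams <- function(x, includeNormStats = TRUE) {
  if (is(x, "UNetSpec")) x <- buildUnet(x, seed = 0L)
  stopifnot(is(x, "UNetModel"))
  length(x@weights) + if (includeNormStats) length(x@stats) else 0L
}

#' Per-layer architecture summary
#'
#' Closed-form layer table of the architecture: one row per parameterised
#' layer with its kernel, channel fan-in/out, optimised parameter count and
#' batch-norm statistic count. The column sums provide an independent check
#' of [countTrainableParams()]; [writeArchitectureSummary()] exports the
#' table as plain text.
#'
#' @param spec a [UNetSpec-class].
#' @return a `data.frame` with columns `layer`, `kernel`, `cin`, `cout`,
#'   `params`, `stats`.
#' @export
unetLayerTable <- function(spec) {
  stopifnot(is(spec, "UNetSpec"))
  validObject(spec)
  b <- spec@baseFilters; d <- spec@depth
  bn <- spec@batchNorm
  f <- b * 2^(0:(d - 1))
  rows <- list()
  add <- function(name, kernel, cin, cout, bnHere = bn) {
    k2 <- prod(kernel)
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, kernel = paste(kernel, collapse = "x"),
      cin = cin, cout = cout,
      params = k2 * cin * cout + cout + if (bnHere) 2L * cout else 0L,
      stats = if (bnHere) 2L * cout else 0L)
  }
  prev <- spec@inputChannels
  for (l in seq_len(d - 1)) {
    add(sprintf("enc%d_conv1", l), c(3, 3), prev, f[l])
    add(sprintf("enc%d_conv2", l), c(3, 3), f[l], f[l])
    prev <- f[l]
  }
  add("bottleneck_conv1", c(3, 3), prev, f[d])
  add("bottleneck_conv2", c(3, 3), f[d], f[d])
  prev <- f[d]
  for (l in rev(seq_len(d - 1))) {
    if (spec@decoderMode == "upconv_concat") {
      add(sprintf("dec%d_upconv", l), c(2, 2), prev, f[l])
      cat_ch <- 2L * f[l]
    } else {
      cat_ch <- prev + f[l]
    }
    add(sprintf("dec%d_conv1", l), c(3, 3), cat_ch, f[l])
    add(sprintf("dec%d_conv2", l), c(3, 3), f[l], f[l])
    prev <- f[l]
  }
  add("head", c(1, 1), prev, 1L, bnHere = FALSE)
  do.call(rbind, rows)
}

#' @describeIn unetLayerTable write the layer table and totals to a plain
#'   text file.
#' @param path output file path.
#' @export
writeArchitectureSummary <- function(spec, path) {
  tab <- unetLayerTable(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(tab, row.names = FALSE)), con)
  writeLines(sprintf("optimised parameters: %d", sum(tab$params)), con)
  writeLines(sprintf("norm statistics:      %d", sum(tab$stats)), con)
  writeLines(sprintf("total:                %d",
                     sum(tab$params) + sum(tab$stats)), con)
  invisible(tab)
}

#' Predict a probability map
#'
#' Runs a forward pass in inference mode (batch-norm uses its moving
#' statistics) on a single-channel image matching the model's input size.
#'
#' @param model a [UNetModel-class].
#' @param image numeric matrix of the model's input size.
#' @return numeric matrix of probabilities in (0, 1).
#' @export
setGeneric("predictMap", function(model, image) standardGeneric("predictMap"))

#' @rdname predictMap
setMethod("predictMap", "UNetModel", function(model, image) {
  sz <- model@spec@inputSize
  if (!all(dim(image) == sz))
    stop(sprintf("image is %d x %d but the network expects %d x %d",
                 nrow(image), ncol(image), sz[1], sz[2]))
  cpp_unet_predict(model@weights, model@stats, .specList(model@spec),
                   image)
})

#' Compare base-filter configurations
#'
#' Trains one network per requested base-filter count on the same pairs and
#' returns the per-epoch training loss and pixel accuracy of each
#' configuration, in long format ready for CSV export or plotting.
#'
#' @param baseList integer vector of base filter counts (e.g.
#'   \code{c(16, 32, 64)}).
#' @param pairs training pairs as returned by [prepareRoiPairs()] or
#'   [prepareCropPairs()].
#' @param epochs epochs per configuration.
#' @param spec template [UNetSpec-class]; its \code{baseFilters} is replaced
#'   by each entry of \code{baseList}.
#' @param config a [TrainConfig-class]; its \code{epochs} is overridden.
#' @param augmentation optional [AugmentationSpec-class].
#' @param seed optional seed applied before each configuration's run.
#' @return `data.frame` with columns `base`, `epoch`, `loss`, `accuracy`.
#' @export
compareFilterConfigs <- function(baseList, pairs, epochs = 60L,
                                 spec = NULL, config = TrainConfig(),
                                 augmentation = NULL, seed = NULL) {
  if (!length(baseList)) stop("baseList must name at least one configuration")
  if (is.null(dim(pairs$images)) || dim(pairs$images)[3] < 1)
    stop("empty dataset")
  if (is.null(spec))
    spec <- UNetSpec(inputSize = dim(pairs$images)[1:2])
  config@epochs <- as.integer(epochs)
  out <- lapply(baseList, function(b) {
    s <- spec
    s@baseFilters <- as.integer(b)
    model <- buildUnet(s, seed = seed)
    fit <- trainNetwork(model, pairs, config, augmentation)
    data.frame(base = b, epoch = seq_len(epochs),
               loss = fit@history$loss, accuracy = fit@history$accuracy)
  })
  do.call(rbind, out)
}
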