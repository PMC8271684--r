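## Central S4 classes. Window coordinates follow one convention everywhere:
## 0-based, half-open [start, stop) intervals on rows and columns, so that
## stop - start is the window side. Conversion to R's 1-based indexing
## happens only inside extractRoi()/pasteBack().

#' Axis-aligned crop window in full-frame coordinates
#'
#' A square (or rectangular) pixel window described by 0-based, half-open
#' row and column intervals \code{[rowStart, rowStop)} x
#' \code{[colStart, colStop)}. The \code{translated} slot records whether
#' boundary clamping had to move the window away from its requested centre.
#'
#' @slot rowStart,rowStop,colStart,colStop integer scalars, 0-based,
#'   half-open bounds.
#' @slot translated logical; \code{TRUE} if the window was shifted to fit
#'   inside the frame.
#' @export
setClass("WindowBox",
  representation(rowStart = "integer", rowStop = "integer",
                 colStart = "integer", colStop = "integer",
                 translated = "logical"),
  prototype(rowStart = 0L, rowStop = 0L, colStart = 0L, colStop = 0L,
            translated = FALSE))

setValidity("WindowBox", function(object) {
  if (object@rowStop <= object@rowStart || object@colStop <= object@colStart)
    return("window intervals must be non-empty (stop > start)")
  if (object@rowStart < 0L || object@colStart < 0L)
    return("window start indices must be >= 0")
  TRUE
})

#' @describeIn WindowBox constructor.
#' @param rowStart,rowStop,colStart,colStop 0-based half-open bounds.
#' @param translated whether boundary clamping moved the window.
#' @export
WindowBox <- function(rowStart, rowStop, colStart, colStop,
                      translated = FALSE) {
  new("WindowBox", rowStart = as.integer(rowStart),
      rowStop = as.integer(rowStop), colStart = as.integer(colStart),
      colStop = as.integer(colStop), translated = translated)
}

#' Synthetic eye-phantom generator settings
#'
#' Describes the population of synthetic infrared eye frames: frame geometry,
#' anatomy size ranges, the three nominal gray levels (dark pupil, mid-gray
#' iris, bright sclera), occluder/glint geometry, and the degradation model
#' (illumination gradient, Gaussian blur, additive noise). All ranges are
#' closed intervals sampled uniformly.
#'
#' @slot imageHeight,imageWidth frame size in pixels (default 512 x 640).
#' @slot irisRadiusRange iris radius range in pixels.
#' @slot pupilFractionRange pupil radius as a fraction of the iris radius.
#' @slot centerJitter maximum offset (pixels, per axis) of the eye centre
#'   from the frame centre.
#' @slot intensityLevels nominal gray values (0-255) for pupil, iris, sclera.
#' @slot occluderParams list of eyelid-arc and retractor-band settings; see
#'   [samplePhantomScene()].
#' @slot glintParams list with \code{max_count}, \code{radius} range and
#'   \code{intensity} of specular spots.
#' @slot blurSigmaRange Gaussian blur sigma range in pixels.
#' @slot noiseSigmaRange additive noise sigma range in gray values.
#' @slot illuminationRange slope range of the multiplicative illumination
#'   gradient (unitless, per half frame).
#' @slot seed optional integer seed used by [makePhantomDataset()].
#' @export
setClass("PhantomSpec",
  representation(imageHeight = "integer", imageWidth = "integer",
                 irisRadiusRange = "numeric", pupilFractionRange = "numeric",
                 centerJitter = "numeric", intensityLevels = "numeric",
                 occluderParams = "list", glintParams = "list",
                 blurSigmaRange = "numeric", noiseSigmaRange = "numeric",
                 illuminationRange = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  rng <- function(x) length(x) == 2L && !anyNA(x) && x[1] <= x[2]
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    return("imageHeight/imageWidth must be positive")
  if (!rng(object@irisRadiusRange) || object@irisRadiusRange[1] <= 0)
    return("irisRadiusRange must be a non-empty closed interval of positive radii")
  if (!rng(object@pupilFractionRange))
    return("pupilFractionRange must be a non-empty closed interval")
  if (object@pupilFractionRange[1] <= 0 || object@pupilFractionRange[2] >= 1)
    return("pupilFractionRange must lie strictly inside (0, 1): the pupil is strictly smaller than the iris")
  if (length(object@intensityLevels) != 3L)
    return("intensityLevels must give pupil, iris and sclera gray values")
  if (!(object@intensityLevels[1] < object@intensityLevels[2] &&
        object@intensityLevels[2] < object@intensityLevels[3]))
    return("intensityLevels must be increasing: pupil < iris < sclera")
  if (!rng(object@blurSigmaRange) || object@blurSigmaRange[1] < 0)
    return("blurSigmaRange must be a non-empty interval of non-negative sigmas")
  if (!rng(object@noiseSigmaRange) || object@noiseSigmaRange[1] < 0)
    return("noiseSigmaRange must be a non-empty interval of non-negative sigmas")
  if (!rng(object@illuminationRange))
    return("illuminationRange must be a non-empty closed interval")
  if (object@centerJitter < 0)
    return("centerJitter must be >= 0")
  TRUE
})

#' @describeIn PhantomSpec constructor with the study's default conditions.
#' @param imageHeight,imageWidth,irisRadiusRange,pupilFractionRange,centerJitter,intensityLevels,occluderParams,glintParams,blurSigmaRange,noiseSigmaRange,illuminationRange,seed see slots.
#' @export
PhantomSpec <- function(imageHeight = 512L, imageWidth = 640L,
                        irisRadiusRange = c(90, 140),
                        pupilFractionRange = c(0.25, 0.55),
                        centerJitter = 120,
                        intensityLevels = c(30, 110, 210),
                        occluderParams = list(
                          upper_prob = 0.7, lower_prob = 0.4,
                          margin_range = c(0.8, 1.3),
                          curvature_range = c(1.5, 3),
                          lid_intensity = c(140, 180),
                          retractor_prob = 0.3,
                          retractor_width = c(6, 18),
                          retractor_intensity = 235),
                        glintParams = list(max_count = 3L,
                                           radius = c(2, 6),
                                           intensity = 250),
                        blurSigmaRange = c(0.5, 2),
                        noiseSigmaRange = c(2, 8),
                        illuminationRange = c(-0.25, 0.25),
                        seed = NA_integer_) {
  new("PhantomSpec", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth),
      irisRadiusRange = as.numeric(irisRadiusRange),
      pupilFractionRange = as.numeric(pupilFractionRange),
      centerJitter = as.numeric(centerJitter),
      intensityLevels = as.numeric(intensityLevels),
      occluderParams = occluderParams, glintParams = glintParams,
      blurSigmaRange = as.numeric(blurSigmaRange),
      noiseSigmaRange = as.numeric(noiseSigmaRange),
      illuminationRange = as.numeric(illuminationRange),
      seed = as.integer(seed))
}

#' A rendered synthetic eye frame with exact ground truth
#'
#' Holds the rendered frame together with its analytic ground truth: the
#' pupil disk, the full limbus-bounded iris disk (pupil included), the
#' derived 350 x 350 ROI window, and the eye centre (the rounded centroid of
#' the iris mask). Ground-truth masks describe the anatomy before occluders,
#' blur and noise are applied, the way a human annotator outlines the full
#' structure contour even under a partially closed lid.
#'
#' @slot image numeric matrix (gray values 0-255).
#' @slot pupilMask,irisMask logical matrices on the frame grid; the pupil
#'   mask is always a subset of the iris mask.
#' @slot roiBox [WindowBox-class] locating the ROI.
#' @slot eyeCenter integer (row, col), 0-based, rounded half-up.
#' @slot params list of the sampled latent geometry.
#' @export
setClass("PhantomScene",
  representation(image = "matrix", pupilMask = "matrix", irisMask = "matrix",
                 roiBox = "WindowBox", eyeCenter = "numeric",
                 params = "list"))

setValidity("PhantomScene", function(object) {
  if (!identical(dim(object@image), dim(object@pupilMask)) ||
      !identical(dim(object@image), dim(object@irisMask)))
    return("image and masks must share one grid")
  if (any(object@pupilMask & !object@irisMask))
    return("pupil mask must be contained in the iris mask")
  d <- dim(object@image)
  b <- object@roiBox
  if (b@rowStop > d[1] || b@colStop > d[2])
    return("roi box must be fully contained in the frame")
  TRUE
})

#' U-Net architecture hyperparameters
#'
#' @slot baseFilters filters in the first encoder block; doubled at each of
#'   the deeper resolution levels.
#' @slot depth number of resolution levels (depth 5 means 4 poolings).
#' @slot inputSize integer (height, width) of the network input.
#' @slot inputChannels input channels (1: grayscale).
#' @slot batchNorm whether convolutions are batch-normalised.
#' @slot leakySlope negative-half slope of the leaky-ReLU activations.
#' @slot decoderMode \code{"upconv_concat"} (2 x 2 up-convolution halving the
#'   feature maps, then skip concatenation; the default) or
#'   \code{"upsample_concat"} (parameter-free nearest-neighbour up-sampling,
#'   then skip concatenation).
#' @export
setClass("UNetSpec",
  representation(baseFilters = "integer", depth = "integer",
                 inputSize = "integer", inputChannels = "integer",
                 batchNorm = "logical", leakySlope = "numeric",
                 decoderMode = "character"))

setValidity("UNetSpec", function(object) {
  if (object@baseFilters < 1L) return("baseFilters must be >= 1")
  if (object@depth < 2L) return("depth must be >= 2")
  if (length(object@inputSize) != 2L || any(object@inputSize < 2L))
    return("inputSize must give (height, width)")
  div <- 2L^(object@depth - 1L)
  if (any(object@inputSize %% div != 0L))
    return(sprintf("inputSize must be divisible by 2^(depth-1) = %d", div))
  if (!object@decoderMode %in% c("upconv_concat", "upsample_concat"))
    return("decoderMode must be 'upconv_concat' or 'upsample_concat'")
  if (object@leakySlope < 0 || object@leakySlope >= 1)
    return("leakySlope must be in [0, 1)")
  TRUE
})

#' @describeIn UNetSpec constructor.
#' @param baseFilters,depth,inputSize,inputChannels,batchNorm,leakySlope,decoderMode see slots.
#' @export
UNetSpec <- function(baseFilters = 16L, depth = 5L, inputSize = c(256L, 256L),
                     inputChannels = 1L, batchNorm = TRUE, leakySlope = 0.3,
                     decoderMode = "upconv_concat") {
  if (length(inputSize) == 1L) inputSize <- rep(inputSize, 2L)
  new("UNetSpec", baseFilters = as.integer(baseFilters),
      depth = as.integer(depth), inputSize = as.integer(inputSize),
      inputChannels = as.integer(inputChannels), batchNorm = batchNorm,
      leakySlope = as.numeric(leakySlope), decoderMode = decoderMode)
}

#' @describeIn UNetSpec the reference architecture: base 16 filters, five
#'   resolution levels, 256 x 256 single-channel input, batch
#'   normalisation, leaky-ReLU 0.3, up-convolution decoder.
#' @export
defaultUNetSpec <- function() UNetSpec()

#' A built (possibly trained) U-Net
#'
#' @slot spec the [UNetSpec-class] the model was built from.
#' @slot weights flat numeric vector of all optimised scalars.
#' @slot stats flat numeric vector of batch-norm moving means/variances.
#' @slot history per-epoch training loss and pixel accuracy (empty before
#'   training).
#' @slot bestEpoch epoch whose weights are stored (best training
#'   cross-entropy), 0 before training.
#' @export
setClass("UNetModel",
  representation(spec = "UNetSpec", weights = "numeric", stats = "numeric",
                 history = "data.frame", bestEpoch = "integer"))

#' Training recipe settings
#'
#' Adam with a constant learning rate and zero decay, pixel-wise binary
#' cross-entropy, and best-weights selection by training-set cross-entropy.
#'
#' @slot learningRate Adam learning rate (default 1e-4).
#' @slot batchSize minibatch size (default 4).
#' @slot epochs training epochs (default 60).
#' @slot seed optional integer seed applied before training.
#' @slot verbose print per-epoch progress.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer", verbose = "logical"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  TRUE
})

#' @describeIn TrainConfig constructor.
#' @param learningRate,batchSize,epochs,seed,verbose see slots.
#' @export
TrainConfig <- function(learningRate = 1e-4, batchSize = 4L, epochs = 60L,
                        seed = NA_integer_, verbose = FALSE) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), verbose = verbose)
}

#' Paired geometric augmentation settings
#'
#' One transform is sampled per image/mask pair and applied identically to
#' both (image bilinearly, mask nearest-neighbour): independent horizontal
#' and vertical reflections, a clockwise rotation in \code{[0, rotationMax)}
#' degrees about the image centre, an integer translation per axis in
#' \code{[-translateMax, translateMax]} pixels, and a zoom factor in
#' \code{zoomRange} about the centre. Regions mapped from outside the canvas
#' are filled with 0.
#'
#' @slot flipH,flipV reflection probabilities (default 0.5 each).
#' @slot rotationMax rotation upper bound in degrees (default 360).
#' @slot translateMax maximum translation magnitude in pixels (default 70).
#' @slot zoomRange closed zoom-factor interval (default \code{c(0.8, 1.2)}).
#' @export
setClass("AugmentationSpec",
  representation(flipH = "numeric", flipV = "numeric", rotationMax = "numeric",
                 translateMax = "numeric", zoomRange = "numeric"))

setValidity("AugmentationSpec", function(object) {
  if (object@flipH < 0 || object@flipH > 1 || object@flipV < 0 || object@flipV > 1)
    return("flip probabilities must be in [0, 1]")
  if (object@translateMax < 0) return("translateMax must be >= 0")
  if (length(object@zoomRange) != 2L || object@zoomRange[1] <= 0 ||
      object@zoomRange[1] > object@zoomRange[2])
    return("zoomRange must be a non-empty interval of positive factors")
  TRUE
})

#' @describeIn AugmentationSpec constructor.
#' @param flipH,flipV,rotationMax,translateMax,zoomRange see slots.
#' @export
AugmentationSpec <- function(flipH = 0.5, flipV = 0.5, rotationMax = 360,
                             translateMax = 70, zoomRange = c(0.8, 1.2)) {
  new("AugmentationSpec", flipH = flipH, flipV = flipV,
      rotationMax = rotationMax, translateMax = translateMax,
      zoomRange = as.numeric(zoomRange))
}

#' Cascade inference settings
#'
#' @slot roiThreshold probability threshold for the eye-localisation map
#'   (default 0.2; strictly greater-than).
#' @slot irisThreshold,pupilThreshold probability thresholds of the fine
#'   stage (defaults 0.5 and 0.15).
#' @slot window side of the square ROI crop in full-frame pixels
#'   (default 350).
#' @slot netInput network input side used when a plain function is supplied
#'   as a model (built models carry their own input size).
#' @slot closingRadius disk radius (pixels, at network resolution) of the
#'   morphological closing applied to binarised maps (default 5).
#' @slot connectivity neighbourhood used for largest-component extraction
#'   (8, fixed).
#' @export
setClass("CascadeConfig",
  representation(roiThreshold = "numeric", irisThreshold = "numeric",
                 pupilThreshold = "numeric", window = "integer",
                 netInput = "integer", closingRadius = "integer",
                 connectivity = "integer"))

setValidity("CascadeConfig", function(object) {
  th <- c(object@roiThreshold, object@irisThreshold, object@pupilThreshold)
  if (any(th <= 0) || any(th >= 1))
    return("thresholds must lie strictly inside (0, 1)")
  if (object@window < 1L) return("window must be positive")
  if (object@closingRadius < 0L) return("closingRadius must be >= 0")
  if (object@connectivity != 8L)
    return("only 8-connectivity is supported")
  TRUE
})

#' @describeIn CascadeConfig constructor.
#' @param roiThreshold,irisThreshold,pupilThreshold,window,netInput,closingRadius,connectivity see slots.
#' @export
CascadeConfig <- function(roiThreshold = 0.2, irisThreshold = 0.5,
                          pupilThreshold = 0.15, window = 350L,
                          netInput = 256L, closingRadius = 5L,
                          connectivity = 8L) {
  new("CascadeConfig", roiThreshold = roiThreshold,
      irisThreshold = irisThreshold, pupilThreshold = pupilThreshold,
      window = as.integer(window), netInput = as.integer(netInput),
      closingRadius = as.integer(closingRadius),
      connectivity = as.integer(connectivity))
}

#' Full-frame result of the two-stage cascade
#'
#' @slot pupilMask,irisMask logical full-frame masks (zero outside the ROI
#'   window).
#' @slot roiBox the [WindowBox-class] used for the fine stage.
#' @slot eyeCenter (row, col) centroid of the localisation mask, 0-based,
#'   rounded half-up; the frame centre when localisation was empty.
#' @slot flags subset of \code{roi_empty}, \code{iris_empty},
#'   \code{pupil_empty}, \code{window_translated}.
#' @export
setClass("CascadeResult",
  representation(pupilMask = "matrix", irisMask = "matrix",
                 roiBox = "WindowBox", eyeCenter = "numeric",
                 flags = "character"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "WindowBox", function(object) {
  cat(sprintf("WindowBox rows [%d, %d) cols [%d, %d)%s\n",
              object@rowStart, object@rowStop, object@colStart,
              object@colStop,
              if (object@translated) " (translated)" else ""))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %d x %d, iris radius [%g, %g] px, pupil fraction [%g, %g]\n",
              object@imageHeight, object@imageWidth,
              object@irisRadiusRange[1], object@irisRadiusRange[2],
              object@pupilFractionRange[1], object@pupilFractionRange[2]))
  cat(sprintf("  gray levels pupil/iris/sclera %g/%g/%g, jitter %g px, blur [%g, %g], noise [%g, %g]\n",
              object@intensityLevels[1], object@intensityLevels[2],
              object@intensityLevels[3], object@centerJitter,
              object@blurSigmaRange[1], object@blurSigmaRange[2],
              object@noiseSigmaRange[1], object@noiseSigmaRange[2]))
})

setMethod("show", "PhantomScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomScene %d x %d, eye centre (%d, %d), iris %d px^2, pupil %d px^2\n",
              d[1], d[2], object@eyeCenter[1], object@eyeCenter[2],
              sum(object@irisMask), sum(object@pupilMask)))
})

setMethod("show", "UNetSpec", function(object) {
  cat(sprintf("UNetSpec base %d, depth %d, input %d x %d x %d, %s, leaky %g, %s\n",
              object@baseFilters, object@depth, object@inputSize[1],
              object@inputSize[2], object@inputChannels,
              if (object@batchNorm) "batch norm" else "no batch norm",
              object@leakySlope, object@decoderMode))
})

setMethod("show", "UNetModel", function(object) {
  show(object@spec)
  cat(sprintf("  %s parameters%s\n",
              format(length(object@weights), big.mark = ","),
              if (object@bestEpoch > 0L)
                sprintf(", trained (best epoch %d)", object@bestEpoch)
              else ", untrained"))
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult centre (%d, %d), iris %d px^2, pupil %d px^2%s\n",
              object@eyeCenter[1], object@eyeCenter[2],
              sum(object@irisMask), sum(object@pupilMask),
              if (length(object@flags))
                paste0(", flags: ", paste(object@flags, collapse = ", "))
              else ""))
})
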