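## Training-pair preparation and the training recipe. Three networks are
## trained from one frame collection: the eye-localisation net sees whole
## frames with the merged iris-and-pupil mask as target, the iris and pupil
## nets see the 350 x 350 ROI crop with the respective structure mask.
## All pairs are brought to the network input size (images bilinear, masks
## nearest-neighbour then re-binarised).

# accept a list of matrices or an H x W x N array; return a list of matrices
.asFrameList <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  if (is.matrix(x)) return(list(x))
  stop("expected a matrix, a list of matrices, or an H x W x N array")
}

.stackPairs <- function(imgs, msks) {
  d <- dim(imgs[[1]])
  list(images = array(unlist(imgs, use.names = FALSE), c(d, length(imgs))),
       masks = array(as.numeric(unlist(msks, use.names = FALSE)),
                     c(d, length(msks))))
}

#' Prepare eye-localisation training pairs
#'
#' Targets for the localisation network are the union of the iris and pupil
#' masks (with the disk convention the union equals the iris disk). Frames
#' are resized bilinearly to \code{size}; masks nearest-neighbour and
#' re-binarised.
#'
#' @param frames,irisMasks,pupilMasks full-resolution frames and aligned
#'   masks (lists of matrices or H x W x N arrays).
#' @param size network input size (rows, cols).
#' @return list with 3-d arrays \code{images} (gray values scaled to
#'   \code{[0, 1]}) and \code{masks} (0/1).
#' @export
prepareRoiPairs <- function(frames, irisMasks, pupilMasks,
                            size = c(256L, 256L)) {
  frames <- .asFrameList(frames)
  irisMasks <- .asFrameList(irisMasks)
  pupilMasks <- .asFrameList(pupilMasks)
  stopifnot(length(frames) == length(irisMasks),
            length(frames) == length(pupilMasks))
  imgs <- vector("list", length(frames))
  msks <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), dim(irisMasks[[i]])) ||
        !identical(dim(frames[[i]]), dim(pupilMasks[[i]])))
      stop(sprintf("frame %d and its masks have different shapes", i))
    merged <- .asMask(irisMasks[[i]]) | .asMask(pupilMasks[[i]])
    imgs[[i]] <- resizeImageBilinear(frames[[i]], size) / 255
    msks[[i]] <- resizeMaskNearest(merged, size)
  }
  .stackPairs(imgs, msks)
}

#' Prepare ROI-crop training pairs for one structure
#'
#' Crops the ROI window from each frame and its structure mask (no
#' resampling in the crop itself), then resizes to the network input size.
#' Boxes must already lie inside the frame; clamping is the caller's job.
#'
#' @param frames full-resolution frames.
#' @param masks aligned structure masks (iris or pupil).
#' @param roiBoxes list of [WindowBox-class] objects, one per frame.
#' @param size network input size (rows, cols).
#' @return list with 3-d arrays \code{images} and \code{masks} as in
#'   [prepareRoiPairs()]. An all-zero mask inside a box is legal and kept.
#' @export
prepareCropPairs <- function(frames, masks, roiBoxes, size = c(256L, 256L)) {
  frames <- .asFrameList(frames)
  masks <- .asFrameList(masks)
  stopifnot(length(frames) == length(masks),
            length(frames) == length(roiBoxes))
  imgs <- vector("list", length(frames))
  msks <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), dim(masks[[i]])))
      stop(sprintf("frame %d and its mask have different shapes", i))
    crop_i <- extractRoi(frames[[i]], roiBoxes[[i]])
    crop_m <- extractRoi(.asMask(masks[[i]]) * 1, roiBoxes[[i]])
    imgs[[i]] <- resizeImageBilinear(crop_i, size) / 255
    msks[[i]] <- resizeMaskNearest(crop_m, size)
  }
  .stackPairs(imgs, msks)
}

#' Apply one sampled augmentation transform to an image/mask pair
#'
#' Samples (or takes) a single geometric transform and applies it
#' identically to both members of the pair: the image is interpolated
#' bilinearly, the mask nearest-neighbour so it stays binary. Rotation and
#' zoom act about the image centre; regions mapped from outside the canvas
#' are filled with 0. Sampling order (via R's RNG): horizontal flip,
#' vertical flip, rotation angle, row translation, column translation, zoom.
#'
#' @param image numeric matrix.
#' @param mask logical or 0/1 matrix of the same shape.
#' @param spec an [AugmentationSpec-class].
#' @param transform optional explicit transform: a list with \code{flipH},
#'   \code{flipV}, \code{angle} (degrees clockwise), \code{ty}, \code{tx}
#'   (pixels, rows/cols), \code{zoom}. When supplied, nothing is sampled.
#' @return list with \code{image}, \code{mask} (logical) and the
#'   \code{transform} used.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
#' tr <- list(flipH = FALSE, flipV = FALSE, angle = 180, ty = 0, tx = 0, zoom = 1)
#' which(augmentPair(m * 10, m, transform = tr)$mask)  # opposite corner
#' @export
augmentPair <- function(image, mask, spec = AugmentationSpec(),
                        transform = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  mask <- .asMask(mask)
  if (is.null(transform)) {
    t_max <- spec@translateMax
    transform <- list(
      flipH = runif(1) < spec@flipH,
      flipV = runif(1) < spec@flipV,
      angle = runif(1) * spec@rotationMax,
      ty = floor(runif(1) * (2 * t_max + 1)) - t_max,
      tx = floor(runif(1) * (2 * t_max + 1)) - t_max,
      zoom = runif(1, spec@zoomRange[1], spec@zoomRange[2]))
  }
  tr <- transform
  img2 <- cpp_warp(image, tr$flipH, tr$flipV, tr$angle, tr$tx, tr$ty,
                   tr$zoom, nearest = FALSE)
  msk2 <- cpp_warp(mask * 1, tr$flipH, tr$flipV, tr$angle, tr$tx, tr$ty,
                   tr$zoom, nearest = TRUE)
  list(image = img2, mask = msk2 > 0.5, transform = tr)
}

#' Optimisation steps per epoch (ceiling division)
#' @param n number of training pairs.
#' @param batchSize minibatch size.
#' @return integer step count.
#' @export
stepsPerEpoch <- function(n, batchSize) as.integer(ceiling(n / batchSize))

#' Train a network
#'
#' Runs the training recipe: minibatch Adam (constant learning rate, zero
#' decay) on pixel-wise binary cross-entropy, with the augmentation
#' transforms sampled on the fly per pair and epoch. The returned model
#' carries the weights of the epoch with the lowest training cross-entropy
#' (best weights are selected on the training set; no validation split is
#' held out) together with the per-epoch history.
#'
#' @param model an untrained or pre-trained [UNetModel-class].
#' @param pairs training pairs from [prepareRoiPairs()] /
#'   [prepareCropPairs()].
#' @param config a [TrainConfig-class].
#' @param augmentation an [AugmentationSpec-class], or NULL to train
#'   without augmentation.
#' @return the trained [UNetModel-class]; \code{model@history} has one row
#'   per epoch (\code{epoch}, \code{loss}, \code{accuracy} - pixel accuracy
#'   at threshold 0.5).
#' @export
trainNetwork <- function(model, pairs, config = TrainConfig(),
                         augmentation = NULL) {
  stopifnot(is(model, "UNetModel"), is(config, "TrainConfig"))
  validObject(config)
  d <- dim(pairs$images)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("empty dataset: pairs$images must be a non-empty H x W x N array")
  sz <- model@spec@inputSize
  if (d[1] != sz[1] || d[2] != sz[2])
    stop(sprintf("pairs are %d x %d but the network expects %d x %d",
                 d[1], d[2], sz[1], sz[2]))
  if (!identical(dim(pairs$masks), d))
    stop("pairs$masks must match pairs$images in shape")
  message("note: best weights are selected on the training set; ",
          "consider holding out a validation split")
  augment <- !is.null(augmentation)
  augspec <- if (augment) {
    list(flip_h = augmentation@flipH, flip_v = augmentation@flipV,
         rotation_max = augmentation@rotationMax,
         translate_max = augmentation@translateMax,
         zoom_min = augmentation@zoomRange[1],
         zoom_max = augmentation@zoomRange[2])
  } else list()
  fit <- .withSeed(config@seed,
    cpp_unet_train(model@weights, model@stats, .specList(model@spec),
                   as.numeric(pairs$images), as.numeric(pairs$masks),
                   d[3], config@epochs, config@batchSize,
                   config@learningRate, augment, augspec, config@verbose))
  model@weights <- fit$weights
  model@stats <- fit$stats
  model@history <- data.frame(epoch = seq_len(config@epochs),
                              loss = fit$loss, accuracy = fit$accuracy)
  model@bestEpoch <- as.integer(fit$best_epoch)
  attr(model@history, "steps_per_epoch") <- fit$steps_per_epoch
  model
}
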