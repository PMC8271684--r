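## The two-stage inference pipeline. Stage one locates the eye on the
## down-scaled full frame and yields a clamped 350 x 350 window; stage two
## segments iris and pupil inside that window and pastes the masks back
## into full-frame coordinates. Binary masks are always rescaled
## nearest-neighbour AFTER thresholding, so they stay binary throughout.

#' Threshold a probability map
#'
#' Strict inequality: a pixel is foreground iff its probability is
#' strictly greater than the threshold.
#'
#' @param probMap numeric matrix with values in \code{[0, 1]}.
#' @param threshold probability threshold.
#' @return logical matrix.
#' @examples
#' binarizeMap(matrix(c(0.1, 0.16, 0.5), 1), 0.15)  # FALSE TRUE TRUE
#' @export
binarizeMap <- function(probMap, threshold) {
  if (anyNA(probMap) || min(probMap) < 0 || max(probMap) > 1)
    stop("probability map must have values in [0, 1]")
  probMap > threshold
}

#' Morphological cleanup of a binary mask
#'
#' Closes the mask with a disk structuring element and keeps only the
#' largest 8-connected component, discarding small spurious detections. An
#' equal-size tie is broken towards the component whose minimum (row, col)
#' pixel is lexicographically smallest. An empty mask stays empty.
#'
#' @param mask logical or 0/1 matrix.
#' @param closingRadius disk radius of the closing in pixels; 0 skips the
#'   closing.
#' @param connectivity pixel neighbourhood (8 only).
#' @return logical matrix.
#' @export
postprocessMask <- function(mask, closingRadius = 5L, connectivity = 8L) {
  mask <- .asMask(mask)
  if (connectivity != 8L) stop("only 8-connectivity is supported")
  if (!any(mask)) return(mask)
  if (closingRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  lab <- cpp_label8(array(as.integer(mask), dim(mask)))
  sizes <- tabulate(lab)
  if (!length(sizes)) return(mask & FALSE)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lexicographic (row, col) of each candidate's first pixel; labels are
    # assigned in column-major scan order, so compare (minrow, mincol)
    H <- nrow(mask)
    key <- vapply(best, function(b) {
      idx <- which(lab == b)
      rows <- (idx - 1L) %% H
      rmin <- min(rows)
      cmin <- min((idx[rows == rmin] - 1L) %/% H)
      rmin * ncol(mask) + cmin
    }, numeric(1))
    best <- best[which.min(key)]
  }
  lab == best
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates. With
#' \code{rounded = TRUE} (default) the mean is rounded half-up to integer
#' pixel coordinates; the unrounded centroid is used for the eye-centre
#' distance metric.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @param rounded round half-up to integers.
#' @return numeric (row, col), 0-based.
#' @export
maskCentroid <- function(mask, rounded = TRUE) {
  mask <- .asMask(mask)
  ctr <- .maskCentroidRaw(mask)
  if (rounded) floor(ctr + 0.5) else ctr
}

#' Clamp a square window inside the frame
#'
#' Places a window of side \code{window} with its top-left corner at
#' \code{center - floor(window/2)} per axis, then translates it minimally
#' along each axis so that it lies fully inside the frame (the behaviour
#' used when the eye sits near the frame border). The returned box records
#' whether any translation was needed.
#'
#' @param center numeric (row, col), 0-based.
#' @param window window side in pixels.
#' @param frameShape integer (rows, cols) of the frame.
#' @return a [WindowBox-class].
#' @examples
#' clampWindow(c(256, 320), 350, c(512, 640))  # rows [81, 431) cols [145, 495)
#' clampWindow(c(10, 320), 350, c(512, 640))   # rows [0, 350), translated
#' @export
clampWindow <- function(center, window, frameShape) {
  window <- as.integer(window)
  if (window > min(frameShape))
    stop("window is larger than the frame")
  start <- floor(center) - floor(window / 2)
  lo <- pmax(start, 0)
  hi <- pmin(lo, frameShape - window)
  translated <- any(hi != start)
  WindowBox(hi[1], hi[1] + window, hi[2], hi[2] + window,
            translated = translated)
}

#' Extract a window from a frame
#'
#' Pure copy of the sub-image under the box; no resampling.
#'
#' @param frame numeric or logical matrix.
#' @param box a [WindowBox-class] fully inside the frame.
#' @return matrix of the box extents.
#' @export
extractRoi <- function(frame, box) {
  d <- dim(frame)
  if (box@rowStart < 0L || box@colStart < 0L ||
      box@rowStop > d[1] || box@colStop > d[2])
    stop("box exceeds the frame; clamp it first")
  frame[(box@rowStart + 1L):box@rowStop,
        (box@colStart + 1L):box@colStop, drop = FALSE]
}

#' Paste an ROI mask back into full-frame coordinates
#'
#' @param maskRoi logical or 0/1 matrix whose extents equal the box sides.
#' @param box the [WindowBox-class] the ROI was extracted with.
#' @param frameShape integer (rows, cols) of the full frame.
#' @return logical full-frame matrix, zero outside the box.
#' @export
pasteBack <- function(maskRoi, box, frameShape) {
  maskRoi <- .asMask(maskRoi)
  sides <- windowSides(box)
  if (!all(dim(maskRoi) == sides))
    stop(sprintf("ROI mask is %d x %d but the box is %d x %d",
                 nrow(maskRoi), ncol(maskRoi), sides[1], sides[2]))
  out <- matrix(FALSE, frameShape[1], frameShape[2])
  out[(box@rowStart + 1L):box@rowStop,
      (box@colStart + 1L):box@colStop] <- maskRoi
  out
}

# resolve a model argument: a built UNetModel or a plain function that maps
# an input-sized image to a probability matrix (used for oracle models)
.modelInputSize <- function(model, config) {
  if (is(model, "UNetModel")) model@spec@inputSize else
    rep(config@netInput, 2L)
}

.modelPredict <- function(model, image, box = NULL) {
  if (is(model, "UNetModel")) return(predictMap(model, image))
  if (length(formals(model)) >= 2L) model(image, box) else model(image)
}

#' Run the two-stage cascade on one frame
#'
#' Pipeline order: (1) the frame is resized bilinearly to the localisation
#' network's input and predicted; (2) the probability map is thresholded
#' (strictly) at \code{roiThreshold}, closed morphologically, reduced to its
#' largest 8-connected component and up-scaled nearest-neighbour to the full
#' frame; (3) the window is centred on the mask centroid and clamped inside
#' the frame, and the ROI is extracted; (4) the ROI is resized to the fine
#' networks' input; (5) the iris network is applied first, then the pupil
#' network, with thresholds \code{irisThreshold} and \code{pupilThreshold};
#' (6) each fine mask is post-processed, resized nearest-neighbour to the
#' window size and pasted back into full-frame coordinates.
#'
#' Degenerate predictions never abort a run: an empty localisation mask
#' falls back to a frame-centred window and sets the \code{roi_empty} flag;
#' an empty iris or pupil mask yields an empty full-frame mask plus its
#' flag.
#'
#' @param frame full-resolution numeric matrix (gray values 0-255).
#' @param models list with elements \code{roi}, \code{iris}, \code{pupil};
#'   each a [UNetModel-class] or a function mapping an input-sized image
#'   (gray values scaled to \code{[0, 1]}) to a probability matrix.
#' @param config a [CascadeConfig-class].
#' @param roiBox optional frozen [WindowBox-class]; when supplied the
#'   localisation stage is skipped and the fine stage runs inside this
#'   window (the "frozen ROI" mode for video streams).
#' @return a [CascadeResult-class].
#' @export
runCascade <- function(frame, models, config = CascadeConfig(),
                       roiBox = NULL) {
  stopifnot(is.matrix(frame), all(c("roi", "iris", "pupil") %in% names(models)))
  frameShape <- dim(frame)
  if (config@window > min(frameShape))
    stop("configured window exceeds the frame size")
  flags <- character()
  eyeCenter <- floor(c(frameShape[1] / 2, frameShape[2] / 2))

  if (is.null(roiBox)) {
    sz <- .modelInputSize(models$roi, config)
    small <- resizeImageBilinear(frame, sz) / 255
    prob <- .modelPredict(models$roi, small)
    roiMask <- postprocessMask(binarizeMap(prob, config@roiThreshold),
                               config@closingRadius, config@connectivity)
    if (!any(roiMask)) {
      flags <- c(flags, "roi_empty")
      box <- clampWindow(eyeCenter, config@window, frameShape)
    } else {
      full <- resizeMaskNearest(roiMask, frameShape)
      if (!any(full)) {           # a tiny blob can vanish in the rescale
        flags <- c(flags, "roi_empty")
        box <- clampWindow(eyeCenter, config@window, frameShape)
      } else {
        eyeCenter <- maskCentroid(full)
        box <- clampWindow(eyeCenter, config@window, frameShape)
      }
    }
  } else {
    box <- roiBox
  }
  if (box@translated) flags <- c(flags, "window_translated")

  crop <- extractRoi(frame, box)
  finePred <- function(model, threshold, name) {
    sz <- .modelInputSize(model, config)
    prob <- .modelPredict(model, resizeImageBilinear(crop, sz) / 255, box)
    m <- postprocessMask(binarizeMap(prob, threshold),
                         config@closingRadius, config@connectivity)
    if (!any(m)) {
      flags <<- c(flags, paste0(name, "_empty"))
      matrix(FALSE, frameShape[1], frameShape[2])
    } else {
      pasteBack(resizeMaskNearest(m, windowSides(box)), box, frameShape)
    }
  }
  irisFull <- finePred(models$iris, config@irisThreshold, "iris")
  pupilFull <- finePred(models$pupil, config@pupilThreshold, "pupil")

  new("CascadeResult", pupilMask = pupilFull, irisMask = irisFull,
      roiBox = box, eyeCenter = eyeCenter, flags = flags)
}

#' Ground-truth oracle models for a scene
#'
#' Builds the three model functions that emit the phantom's exact ground
#' truth as probability maps (1 inside the structure, 0 outside) at the
#' requested network resolution. Feeding these to [runCascade()] isolates
#' the geometric pipeline: any loss relative to the ground truth is due to
#' resize quantisation alone.
#'
#' @param scene a [PhantomScene-class].
#' @param config the [CascadeConfig-class] the cascade will run with.
#' @return list with functions \code{roi}, \code{iris}, \code{pupil}; the
#'   fine-stage functions take the crop window as a second argument, which
#'   [runCascade()] supplies.
#' @export
oracleModels <- function(scene, config = CascadeConfig()) {
  sz <- rep(config@netInput, 2L)
  roiFun <- function(image) {
    resizeMaskNearest(scene@irisMask, sz) * 1
  }
  structFun <- function(mask) {
    force(mask)
    function(image, box) {
      resizeMaskNearest(extractRoi(mask * 1, box), sz) * 1
    }
  }
  list(roi = roiFun, iris = structFun(scene@irisMask),
       pupil = structFun(scene@pupilMask))
}
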