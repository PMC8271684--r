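## File formats: 8-bit grayscale PNG for frames and masks (mask foreground
## 255), an overlay PNG for visual review (iris area blue, pupil red drawn
## on top), CSV for manifests/records, and a flat YAML file for run
## configuration. Frames may also arrive as RGB PNGs; they are converted to
## one channel with the Rec.601 luma weights. AVI decoding is not bundled:
## extract frames to a directory of PNGs first (see readFrames).

#' Convert an RGB array to grayscale
#'
#' Rec.601 luma: \code{0.299 R + 0.587 G + 0.114 B}. Grayscale input is
#' returned unchanged.
#'
#' @param x numeric matrix, or H x W x 3 (or x4, alpha ignored) array with
#'   values in \code{[0, 1]} or \code{[0, 255]}.
#' @return numeric matrix on the input scale.
#' @export
rgbToGray <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L)
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) return(x[, , 1])
  stop("expected a matrix or an H x W x 3 array")
}

#' Read ordered frames from a directory
#'
#' Reads every PNG/TIFF in the directory in lexicographic filename order,
#' converts to single-channel gray values on the 0-255 scale, and uses the
#' file name (without extension) as the stable frame id. AVI input is not
#' decoded here; pass a directory of extracted frames instead (e.g.
#' \code{ffmpeg -i video.avi frames/frame_%04d.png}).
#'
#' @param source directory containing the frames.
#' @return list with \code{frames} (list of matrices) and \code{ids}
#'   (character).
#' @export
readFrames <- function(source) {
  if (length(source) == 1L && grepl("\\.avi$", source, ignore.case = TRUE))
    stop("AVI decoding is not bundled; extract the frames to PNG first ",
         "(e.g. with ffmpeg) and pass the directory")
  if (!dir.exists(source)) stop("not a readable directory: ", source)
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  files <- files[!grepl("_(pupil|iris)\\.png$", files)]   # skip mask files
  if (!length(files)) stop("no frames found in ", source)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    path <- file.path(source, files[i])
    img <- tryCatch({
      if (grepl("\\.png$", files[i], ignore.case = TRUE)) {
        png::readPNG(path)
      } else {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF frames needs the 'tiff' package")
        tiff::readTIFF(path)
      }
    }, error = function(e) stop("cannot decode frame ", path, ": ",
                                conditionMessage(e)))
    frames[[i]] <- rgbToGray(img) * 255
  }
  list(frames = frames, ids = sub("\\.[^.]*$", "", files))
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Foreground is written as 255, background as 0; reading thresholds at
#' half intensity so the round trip is exact.
#'
#' @param mask logical or 0/1 matrix.
#' @param path file path.
#' @return `writeMaskPng` returns the path invisibly; `readMaskPng` a
#'   logical matrix.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(.asMask(mask) * 1, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  rgbToGray(png::readPNG(path)) > 0.5
}

#' Compose a review overlay
#'
#' The frame with the predicted iris area tinted blue and the pupil area
#' red drawn on top of it.
#'
#' @param frame numeric matrix (0-255).
#' @param result a [CascadeResult-class].
#' @return H x W x 3 array in \code{[0, 1]}.
#' @export
overlayResult <- function(frame, result) {
  g <- pmin(pmax(frame / 255, 0), 1)
  rgb <- array(g, c(dim(g), 3L))
  iris <- result@irisMask & !result@pupilMask
  r <- rgb[, , 1]; gr <- rgb[, , 2]; b <- rgb[, , 3]
  b[iris] <- 0.6 + 0.4 * g[iris];  r[iris] <- 0.3 * g[iris];  gr[iris] <- 0.3 * g[iris]
  p <- result@pupilMask
  r[p] <- 0.6 + 0.4 * g[p];  gr[p] <- 0.3 * g[p];  b[p] <- 0.3 * g[p]
  rgb[, , 1] <- r; rgb[, , 2] <- gr; rgb[, , 3] <- b
  rgb
}

#' Write the per-frame outputs of a cascade run
#'
#' Writes the pupil and iris masks as PNGs, an overlay PNG, and appends one
#' CSV row (frame id, eye centre, window bounds, flags) to
#' \code{results.csv} in \code{outDir}.
#'
#' @param result a [CascadeResult-class].
#' @param frame the frame the result was computed on.
#' @param outDir output directory (created if missing).
#' @param frameId id used in file names and the CSV row.
#' @return the CSV row, invisibly.
#' @export
writeOutputs <- function(result, frame, outDir, frameId = "frame") {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  writeMaskPng(result@pupilMask, file.path(outDir, paste0(frameId, "_pupil.png")))
  writeMaskPng(result@irisMask, file.path(outDir, paste0(frameId, "_iris.png")))
  png::writePNG(overlayResult(frame, result),
                file.path(outDir, paste0(frameId, "_overlay.png")))
  b <- result@roiBox
  row <- data.frame(frame_id = frameId,
                    center_row = result@eyeCenter[1],
                    center_col = result@eyeCenter[2],
                    row_start = b@rowStart, row_stop = b@rowStop,
                    col_start = b@colStart, col_stop = b@colStop,
                    flags = paste(result@flags, collapse = ";"))
  csv <- file.path(outDir, "results.csv")
  utils::write.table(row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv),
                     append = file.exists(csv))
  invisible(row)
}

#' Save / load a run configuration
#'
#' A flat YAML file whose keys mirror the configuration classes:
#' \code{cascade.*} ([CascadeConfig-class]), \code{train.*}
#' ([TrainConfig-class]), \code{augment.*} ([AugmentationSpec-class]) and
#' \code{seed}. Every threshold and size field round-trips unchanged.
#'
#' @param config named list with elements \code{cascade}, \code{train},
#'   \code{augment} (the S4 objects) and \code{seed}.
#' @param path YAML file path.
#' @return `writeRunConfig` the path invisibly; `readRunConfig` the list of
#'   reconstructed objects.
#' @export
writeRunConfig <- function(config, path) {
  cc <- config$cascade %||% CascadeConfig()
  tc <- config$train %||% TrainConfig()
  au <- config$augment %||% AugmentationSpec()
  out <- list(
    seed = if (is.null(config$seed)) NA else config$seed,
    cascade = list(roi_threshold = cc@roiThreshold,
                   iris_threshold = cc@irisThreshold,
                   pupil_threshold = cc@pupilThreshold,
                   window = cc@window, net_input = cc@netInput,
                   closing_radius = cc@closingRadius,
                   connectivity = cc@connectivity),
    train = list(learning_rate = tc@learningRate, batch_size = tc@batchSize,
                 epochs = tc@epochs),
    augment = list(flip_h = au@flipH, flip_v = au@flipV,
                   rotation_max = au@rotationMax,
                   translate_max = au@translateMax,
                   zoom_min = au@zoomRange[1], zoom_max = au@zoomRange[2]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    seed = if (is.null(y$seed) || is.na(y$seed)) NULL else as.integer(y$seed),
    cascade = CascadeConfig(roiThreshold = y$cascade$roi_threshold,
                            irisThreshold = y$cascade$iris_threshold,
                            pupilThreshold = y$cascade$pupil_threshold,
                            window = y$cascade$window,
                            netInput = y$cascade$net_input,
                            closingRadius = y$cascade$closing_radius,
                            connectivity = y$cascade$connectivity),
    train = TrainConfig(learningRate = y$train$learning_rate,
                        batchSize = y$train$batch_size,
                        epochs = y$train$epochs),
    augment = AugmentationSpec(flipH = y$augment$flip_h,
                               flipV = y$augment$flip_v,
                               rotationMax = y$augment$rotation_max,
                               translateMax = y$augment$translate_max,
                               zoomRange = c(y$augment$zoom_min,
                                             y$augment$zoom_max)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
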