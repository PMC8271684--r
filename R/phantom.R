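## Synthetic infrared eye-phantom generator. A scene is rendered in a fixed
## order - pupil/iris/sclera disks, occluders, glints, illumination gradient,
## Gaussian blur, additive noise - while the ground-truth masks are taken
## from the clean analytic geometry BEFORE any occlusion, the way an
## annotator outlines the full anatomical contour.

# run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  force(expr)
}

# center-sampling rasterisation: a pixel belongs to the disk iff its centre
# (integer 0-based coordinates) lies inside or on the circle
.rasterDisk <- function(H, W, cr, cc, radius) {
  rr <- matrix(0:(H - 1), H, W)
  ccx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  (rr - cr)^2 + (ccx - cc)^2 <= radius^2
}

# centroid of a logical mask in 0-based coordinates; exact = unrounded
.maskCentroidRaw <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stop("no foreground")
  H <- nrow(mask)
  c(mean((idx - 1L) %% H), mean((idx - 1L) %/% H))
}

.runif1 <- function(range) runif(1, range[1], range[2])

#' Sample one synthetic eye scene
#'
#' Renders a single ETS-like infrared frame and its exact ground truth.
#' The image is drawn as three nominal gray levels (dark pupil disk, mid-gray
#' iris disk, bright sclera), then degraded in a fixed order: eyelid arcs and
#' a bright retractor band, specular glints, a multiplicative linear
#' illumination gradient, Gaussian blur, and additive Gaussian noise
#' (clamped to 0-255). Masks are computed from the clean disk geometry
#' before the degradations, and the iris mask is the full limbus-bounded
#' disk (it contains the pupil mask).
#'
#' @param spec a [PhantomSpec-class].
#' @param seed optional integer; when given, the scene is sampled under this
#'   seed and the caller's RNG state is restored (two calls with the same
#'   seed are bit-identical).
#' @param roiWindow side of the derived ROI window in pixels (350 for the
#'   full-size frame geometry).
#' @return a [PhantomScene-class].
#' @examples
#' sc <- samplePhantomScene(PhantomSpec(), seed = 1)
#' sum(irisMask(sc)) > sum(pupilMask(sc))
#' @export
samplePhantomScene <- function(spec, seed = NULL, roiWindow = 350L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .withSeed(seed, {
    H <- spec@imageHeight
    W <- spec@imageWidth
    irisR <- .runif1(spec@irisRadiusRange)
    pupilR <- irisR * .runif1(spec@pupilFractionRange)
    ecr <- (H / 2) + runif(1, -spec@centerJitter, spec@centerJitter)
    ecc <- (W / 2) + runif(1, -spec@centerJitter, spec@centerJitter)

    irisM <- .rasterDisk(H, W, ecr, ecc, irisR)
    pupilM <- .rasterDisk(H, W, ecr, ecc, pupilR)
    if (!any(irisM)) stop("degenerate scene: iris entirely outside the frame")

    lv <- spec@intensityLevels
    img <- matrix(lv[3], H, W)
    img[irisM] <- lv[2]
    img[pupilM] <- lv[1]

    rows <- matrix(0:(H - 1), H, W)
    cols <- matrix(0:(W - 1), H, W, byrow = TRUE)

    oc <- spec@occluderParams
    lid_int <- .runif1(oc$lid_intensity)
    upper <- runif(1) < oc$upper_prob
    if (upper) {
      d <- .runif1(oc$margin_range) * irisR
      curv <- .runif1(oc$curvature_range) * irisR
      bound <- (ecr - d) + (cols - ecc)^2 / (2 * curv)
      img[rows < bound] <- lid_int
      if (runif(1) < oc$retractor_prob) {
        w <- .runif1(oc$retractor_width)
        img[abs(rows - bound) < w / 2] <- oc$retractor_intensity
      }
    }
    if (runif(1) < oc$lower_prob) {
      d2 <- .runif1(oc$margin_range) * irisR
      curv2 <- .runif1(oc$curvature_range) * irisR
      bound2 <- (ecr + d2) - (cols - ecc)^2 / (2 * curv2)
      img[rows > bound2] <- lid_int
    }

    gl <- spec@glintParams
    nglint <- floor(runif(1) * (gl$max_count + 1))
    glints <- list()
    if (nglint > 0) for (g in seq_len(nglint)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.8 * irisR)
      gr <- .runif1(gl$radius)
      gcr <- ecr + rad * sin(ang)
      gcc <- ecc + rad * cos(ang)
      img[.rasterDisk(H, W, gcr, gcc, gr)] <- gl$intensity
      glints[[g]] <- c(row = gcr, col = gcc, radius = gr)
    }

    gx <- .runif1(spec@illuminationRange)
    gy <- .runif1(spec@illuminationRange)
    img <- img * (1 + gx * (cols - (W - 1) / 2) / W + gy * (rows - (H - 1) / 2) / H)

    bsig <- .runif1(spec@blurSigmaRange)
    if (bsig > 0) img <- EBImage::gblur(img, sigma = bsig)

    nsig <- .runif1(spec@noiseSigmaRange)
    if (nsig > 0) img <- img + matrix(rnorm(H * W, 0, nsig), H, W)
    img <- pmin(pmax(img, 0), 255)

    ec <- floor(.maskCentroidRaw(irisM) + 0.5)
    box <- deriveRoiBox(irisM, window = min(roiWindow, H, W))
    new("PhantomScene", image = img, pupilMask = pupilM, irisMask = irisM,
        roiBox = box, eyeCenter = ec,
        params = list(iris_radius = irisR, pupil_radius = pupilR,
                      center = c(ecr, ecc), upper_lid = upper,
                      glints = glints, blur_sigma = bsig,
                      noise_sigma = nsig, illumination = c(gx, gy)))
  })
}

#' Locate the ROI window from a ground-truth mask
#'
#' Centres a square window of the given side on the (half-up rounded)
#' centroid of the mask foreground, then translates it minimally so it lies
#' fully inside the frame (the same clamping rule used at inference time by
#' [clampWindow()]).
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @param window window side in pixels; must not exceed either frame
#'   dimension.
#' @return a [WindowBox-class].
#' @examples
#' m <- matrix(FALSE, 512, 640); m[250:262, 314:326] <- TRUE
#' deriveRoiBox(m, 350)  # rows [81, 431), cols [145, 495)
#' @export
deriveRoiBox <- function(mask, window = 350L) {
  mask <- .asMask(mask)
  if (!any(mask)) stop("no foreground")
  ctr <- floor(.maskCentroidRaw(mask) + 0.5)
  clampWindow(ctr, window, dim(mask))
}

#' Write a synthetic dataset to disk
#'
#' Renders \code{nFrames} scenes and writes, per scene, the frame and the
#' two ground-truth masks as 8-bit grayscale PNGs (mask foreground 255),
#' plus one manifest row. The manifest column order is fixed:
#' \code{frame_id, image, pupil_mask, iris_mask, center_row, center_col,
#' row_start, row_stop, col_start, col_stop, iris_radius, pupil_radius,
#' center_row_exact, center_col_exact} (window bounds 0-based half-open).
#'
#' @param spec a [PhantomSpec-class].
#' @param nFrames number of scenes (>= 1).
#' @param outDir output directory (created if missing).
#' @param seed integer seed; defaults to the spec's \code{seed} slot.
#' @return the manifest `data.frame`, invisibly; also written to
#'   \code{manifest.csv}.
#' @export
makePhantomDataset <- function(spec, nFrames, outDir,
                               seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  .withSeed(seed, {
    rows <- vector("list", nFrames)
    for (i in seq_len(nFrames)) {
      sc <- samplePhantomScene(spec)
      id <- sprintf("frame_%04d", i)
      fi <- paste0(id, ".png")
      fp <- paste0(id, "_pupil.png")
      fir <- paste0(id, "_iris.png")
      png::writePNG(round(sc@image) / 255, file.path(outDir, fi))
      png::writePNG(sc@pupilMask * 1, file.path(outDir, fp))
      png::writePNG(sc@irisMask * 1, file.path(outDir, fir))
      b <- sc@roiBox
      rows[[i]] <- data.frame(
        frame_id = id, image = fi, pupil_mask = fp, iris_mask = fir,
        center_row = sc@eyeCenter[1], center_col = sc@eyeCenter[2],
        row_start = b@rowStart, row_stop = b@rowStop,
        col_start = b@colStart, col_stop = b@colStop,
        iris_radius = sc@params$iris_radius,
        pupil_radius = sc@params$pupil_radius,
        center_row_exact = sc@params$center[1],
        center_col_exact = sc@params$center[2])
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    invisible(manifest)
  })
}

# coerce a mask argument to logical and check it is binary
.asMask <- function(m) {
  if (is.logical(m)) return(m)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1)))
    stop("mask must be binary (0/1 or logical)")
  array(m == 1, dim = dim(m))
}
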