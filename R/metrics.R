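## Evaluation metrics. All metrics are computed on full-frame masks after
## paste-back, so that a mislocated ROI shows up in the scores. Degenerate
## cases (an empty prediction, or two empty masks) yield NA - the
## "undefined" sentinel - which summaries exclude but count as failures.

.pairCounts <- function(A, G) {
  A <- .asMask(A); G <- .asMask(G)
  if (!identical(dim(A), dim(G)))
    stop("masks must have identical dimensions")
  c(a = sum(A), g = sum(G), inter = sum(A & G))
}

#' Dice coefficient
#'
#' \code{2 |A n G| / (|A| + |G|)}: the overlap between a predicted
#' segmentation A and a reference G. NA when both masks are empty.
#'
#' @param A,G binary masks on the same grid (prediction and ground truth).
#' @return numeric in \code{[0, 1]}, or NA.
#' @export
diceCoefficient <- function(A, G) {
  n <- .pairCounts(A, G)
  if (n["a"] + n["g"] == 0) return(NA_real_)
  unname(2 * n["inter"] / (n["a"] + n["g"]))
}

#' Szymkiewicz-Simpson (overlap) coefficient
#'
#' \code{|A n G| / min(|A|, |G|)}: equals 1 whenever one region contains
#' the other. NA when either mask is empty.
#'
#' @inheritParams diceCoefficient
#' @return numeric in \code{[0, 1]}, or NA.
#' @export
simpsonCoefficient <- function(A, G) {
  n <- .pairCounts(A, G)
  if (n["a"] == 0 || n["g"] == 0) return(NA_real_)
  unname(n["inter"] / min(n["a"], n["g"]))
}

#' Intersection over Union (Jaccard index)
#'
#' \code{|A n G| / |A u G|}. NA when both masks are empty.
#'
#' @inheritParams diceCoefficient
#' @return numeric in \code{[0, 1]}, or NA.
#' @export
iouCoefficient <- function(A, G) {
  n <- .pairCounts(A, G)
  u <- n["a"] + n["g"] - n["inter"]
  if (u == 0) return(NA_real_)
  unname(n["inter"] / u)
}

#' Hausdorff distance between mask contours
#'
#' Symmetric Hausdorff distance, in pixels, between the contour point sets
#' of the two masks. A contour pixel is a foreground pixel with at least
#' one 4-neighbour outside the mask (out-of-grid neighbours count as
#' background). NA when either mask is empty.
#'
#' @inheritParams diceCoefficient
#' @return distance in pixels, or NA.
#' @examples
#' a <- matrix(FALSE, 5, 5); a[1, 1] <- TRUE
#' b <- matrix(FALSE, 5, 5); b[4, 5] <- TRUE
#' hausdorffDistance(a, b)  # 5
#' @export
hausdorffDistance <- function(A, G) {
  A <- .asMask(A); G <- .asMask(G)
  if (!identical(dim(A), dim(G)))
    stop("masks must have identical dimensions")
  cpp_hausdorff(array(as.integer(A), dim(A)), array(as.integer(G), dim(G)))
}

#' Eye-centre localisation error
#'
#' Euclidean distance, in pixels, between the (unrounded) centroid of the
#' predicted localisation mask and the reference eye centre. NA for an
#' empty prediction.
#'
#' @param predMask predicted binary mask.
#' @param gtCenter reference (row, col), 0-based.
#' @return distance in pixels, or NA.
#' @export
centerDistance <- function(predMask, gtCenter) {
  predMask <- .asMask(predMask)
  if (!any(predMask)) return(NA_real_)
  ctr <- maskCentroid(predMask, rounded = FALSE)
  sqrt(sum((ctr - gtCenter)^2))
}

#' Score cascade results against ground truth
#'
#' Builds one evaluation record per frame and structure from full-frame
#' masks: Dice, Szymkiewicz-Simpson, IoU, contour Hausdorff distance, the
#' eye-centre distance (attached to every record of a frame), and the
#' result flags.
#'
#' @param results list of [CascadeResult-class] objects.
#' @param scenes list of [PhantomScene-class] objects (or any objects with
#'   \code{irisMask}/\code{pupilMask}/\code{eyeCenter} accessors), aligned
#'   with \code{results}.
#' @param frameIds optional character ids; defaults to the index.
#' @return a `data.frame` with columns `frame_id`, `structure`, `dice`,
#'   `simpson`, `iou`, `hausdorff`, `center_distance`, `flags`.
#' @export
evaluateCascade <- function(results, scenes, frameIds = NULL) {
  stopifnot(length(results) == length(scenes))
  if (is.null(frameIds)) frameIds <- sprintf("frame_%04d", seq_along(results))
  rows <- vector("list", 2L * length(results))
  for (i in seq_along(results)) {
    res <- results[[i]]
    sc <- scenes[[i]]
    cd <- if (any(res@irisMask) || any(res@pupilMask) ||
              !"roi_empty" %in% res@flags) {
      sqrt(sum((res@eyeCenter - eyeCenter(sc))^2))
    } else NA_real_
    pairs <- list(iris = list(irisMask(res), irisMask(sc)),
                  pupil = list(pupilMask(res), pupilMask(sc)))
    for (s in names(pairs)) {
      A <- pairs[[s]][[1]]; G <- pairs[[s]][[2]]
      rows[[2L * (i - 1L) + match(s, names(pairs))]] <- data.frame(
        frame_id = frameIds[i], structure = s,
        dice = diceCoefficient(A, G),
        simpson = simpsonCoefficient(A, G),
        iou = iouCoefficient(A, G),
        hausdorff = hausdorffDistance(A, G),
        center_distance = cd,
        flags = paste(res@flags, collapse = ";"))
    }
  }
  do.call(rbind, rows)
}

#' Summarise evaluation records
#'
#' Median and quartiles (linear-interpolation quantile rule, R type 7) per
#' structure and metric, computed over the defined records only; undefined
#' (NA) records are excluded from the statistics but counted and reported
#' in \code{n_undefined}.
#'
#' @param records a `data.frame` from [evaluateCascade()] (or with the same
#'   metric columns and a `structure` column).
#' @param metrics metric columns to summarise.
#' @return a `data.frame` with columns `structure`, `metric`, `median`,
#'   `p25`, `p75`, `n`, `n_undefined`.
#' @export
summarizeEvalRecords <- function(records,
                                 metrics = c("dice", "simpson", "iou",
                                             "hausdorff",
                                             "center_distance")) {
  stopifnot(is.data.frame(records), "structure" %in% names(records))
  metrics <- intersect(metrics, names(records))
  out <- list()
  for (s in unique(records$structure)) {
    sub <- records[records$structure == s, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      def <- v[!is.na(v)]
      if (!length(def) && nrow(sub) > 0 && all(is.na(v)))
        q <- c(NA_real_, NA_real_, NA_real_)
      else
        q <- unname(quantile(def, c(0.5, 0.25, 0.75), type = 7))
      out[[length(out) + 1L]] <- data.frame(
        structure = s, metric = m, median = q[1], p25 = q[2], p75 = q[3],
        n = length(def), n_undefined = sum(is.na(v)))
    }
  }
  res <- do.call(rbind, out)
  if (all(res$n == 0)) stop("all records are undefined")
  res
}
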