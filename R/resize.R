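## Resampling rules, fixed once for the whole pipeline:
## - images are resized bilinearly;
## - binary masks are resized nearest-neighbour with centre sampling
##   (output pixel k, 0-based, reads input pixel floor((k + 0.5) * n/m)),
##   which is exactly invertible on block-constant masks and never creates
##   intermediate gray values.

#' Resize an intensity image bilinearly
#'
#' @param image numeric matrix.
#' @param outDim integer (rows, cols) of the output.
#' @return numeric matrix of size \code{outDim}.
#' @export
resizeImageBilinear <- function(image, outDim) {
  outDim <- as.integer(outDim)
  if (all(dim(image) == outDim)) return(image)
  out <- EBImage::resize(image, w = outDim[1], h = outDim[2],
                         filter = "bilinear")
  matrix(as.numeric(out), outDim[1], outDim[2])
}

#' Resize a binary mask with nearest-neighbour sampling
#'
#' @param mask logical or 0/1 matrix.
#' @param outDim integer (rows, cols) of the output.
#' @return logical matrix of size \code{outDim}.
#' @export
resizeMaskNearest <- function(mask, outDim) {
  mask <- .asMask(mask)
  outDim <- as.integer(outDim)
  if (all(dim(mask) == outDim)) return(mask)
  ri <- pmin(floor((seq_len(outDim[1]) - 0.5) * nrow(mask) / outDim[1]),
             nrow(mask) - 1L) + 1L
  ci <- pmin(floor((seq_len(outDim[2]) - 0.5) * ncol(mask) / outDim[2]),
             ncol(mask) - 1L) + 1L
  mask[ri, ci, drop = FALSE]
}
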