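#' Accessors for scenes and cascade results
#'
#' Slot access for [PhantomScene-class] and [CascadeResult-class] objects.
#'
#' @param x a scene or result object.
#' @return `irisMask`/`pupilMask` return logical matrices, `roiBox` a
#'   [WindowBox-class], `eyeCenter` an integer (row, col) pair (0-based),
#'   `frameImage` the rendered frame, `resultFlags` a character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("irisMask", function(x) standardGeneric("irisMask"))
#' @rdname accessors
#' @export
setGeneric("pupilMask", function(x) standardGeneric("pupilMask"))
#' @rdname accessors
#' @export
setGeneric("roiBox", function(x) standardGeneric("roiBox"))
#' @rdname accessors
#' @export
setGeneric("eyeCenter", function(x) standardGeneric("eyeCenter"))
#' @rdname accessors
#' @export
setGeneric("frameImage", function(x) standardGeneric("frameImage"))
#' @rdname accessors
#' @export
setGeneric("resultFlags", function(x) standardGeneric("resultFlags"))

#' @rdname accessors
setMethod("irisMask", "PhantomScene", function(x) x@irisMask)
#' @rdname accessors
setMethod("pupilMask", "PhantomScene", function(x) x@pupilMask)
#' @rdname accessors
setMethod("roiBox", "PhantomScene", function(x) x@roiBox)
#' @rdname accessors
setMethod("eyeCenter", "PhantomScene", function(x) x@eyeCenter)
#' @rdname accessors
setMethod("frameImage", "PhantomScene", function(x) x@image)

#' @rdname accessors
setMethod("irisMask", "CascadeResult", function(x) x@irisMask)
#' @rdname accessors
setMethod("pupilMask", "CascadeResult", function(x) x@pupilMask)
#' @rdname accessors
setMethod("roiBox", "CascadeResult", function(x) x@roiBox)
#' @rdname accessors
setMethod("eyeCenter", "CascadeResult", function(x) x@eyeCenter)
#' @rdname accessors
setMethod("resultFlags", "CascadeResult", function(x) x@flags)

#' Side length of a window box
#' @param box a [WindowBox-class].
#' @return integer (rows, cols) extents.
#' @export
windowSides <- function(box) {
  c(box@rowStop - box@rowStart, box@colStop - box@colStart)
}
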