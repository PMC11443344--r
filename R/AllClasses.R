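#' @import methods
NULL

#' Ground truth for a synthetic fluorescence leaf image
#'
#' Holds the pixel-level ground truth attached to images produced by
#' [makeLeafImage()]: the leaf support mask, the injured-tissue mask, the
#' realized injury-area ratio and the corresponding grade.
#'
#' @slot leaf_mask logical matrix; `TRUE` on leaf tissue.
#' @slot injury_mask logical matrix; `TRUE` on injured leaf tissue
#'   (always a subset of `leaf_mask`).
#' @slot lk_true numeric scalar in `[0, 1]`; injured-pixel count divided by
#'   leaf-pixel count.
#' @slot grade_true character; one of `"A"`, `"B"`, `"C"`, `"D"`.
#'
#' @seealso [makeLeafImage()], [gradeFromRatio()]
#' @export
setClass("LeafTruth",
  representation(
    leaf_mask   = "matrix",
    injury_mask = "matrix",
    lk_true     = "numeric",
    grade_true  = "character"
  )
)

setValidity("LeafTruth", function(object) {
  msg <- character()
  lm <- object@leaf_mask
  im <- object@injury_mask
  if (!is.logical(lm) || !is.logical(im))
    msg <- c(msg, "masks must be logical matrices")
  if (!identical(dim(lm), dim(im)))
    msg <- c(msg, "leaf_mask and injury_mask dimensions differ")
  if (is.logical(lm) && is.logical(im) && any(im & !lm))
    msg <- c(msg, "injury_mask must be a subset of leaf_mask")
  n_leaf <- sum(lm)
  if (n_leaf > 0 && abs(object@lk_true - sum(im) / n_leaf) > 1e-12)
    msg <- c(msg, "lk_true does not equal |injury_mask| / |leaf_mask|")
  if (!object@grade_true %in% c("A", "B", "C", "D"))
    msg <- c(msg, "grade_true must be one of A, B, C, D")
  if (n_leaf > 0 &&
      object@grade_true != as.character(gradeFromRatio(object@lk_true)$label))
    msg <- c(msg, "grade_true inconsistent with lk_true")
  if (length(msg)) msg else TRUE
})

setClassUnion("LeafTruthOrNULL", c("LeafTruth", "NULL"))

#' Paired pseudo-color and grayscale fluorescence leaf image
#'
#' The central image container: an `H x W x 3` integer RGB raster (the
#' instrument-style pseudo-color rendering, values in 0..255) paired with the
#' `H x W` integer grayscale fluorescence raster it was derived from, plus an
#' identifier and, for synthetic images, the generating ground truth.
#'
#' @slot rgb integer array `H x W x 3`, values in `[0, 255]`.
#' @slot gray integer matrix `H x W`, values in `[0, 255]`.
#' @slot id character identifier.
#' @slot truth a [LeafTruth-class] object or `NULL`.
#'
#' @seealso [makeLeafImage()], [segmentLeaf()], [extractFeatures()]
#' @export
setClass("FluorescenceImage",
  representation(
    rgb   = "array",
    gray  = "matrix",
    id    = "character",
    truth = "LeafTruthOrNULL"
  )
)

setValidity("FluorescenceImage", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "rgb must be an H x W x 3 array")
  if (length(d) == 3L && !identical(d[1:2], dim(object@gray)))
    msg <- c(msg, "rgb and gray must share H x W")
  if (length(d) == 3L && (d[1] < 16L || d[2] < 16L))
    msg <- c(msg, "images must be at least 16 x 16")
  rng <- range(object@rgb, object@gray)
  if (rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(object@id) != 1L)
    msg <- c(msg, "id must be a single string")
  if (!is.null(object@truth) &&
      !identical(dim(object@truth@leaf_mask), dim(object@gray)))
    msg <- c(msg, "truth masks must share the image dimensions")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceImage
#'
#' @param rgb numeric/integer `H x W x 3` array in `[0, 255]`.
#' @param gray numeric/integer `H x W` matrix in `[0, 255]`.
#' @param id single string identifier.
#' @param truth optional [LeafTruth-class].
#' @return A [FluorescenceImage-class] object.
#' @export
FluorescenceImage <- function(rgb, gray, id = "img", truth = NULL) {
  storage.mode(rgb) <- "integer"
  storage.mode(gray) <- "integer"
  new("FluorescenceImage", rgb = rgb, gray = gray, id = as.character(id),
      truth = truth)
}

#' Accessors for FluorescenceImage and LeafTruth
#'
#' `rgbImage()` and `grayImage()` return the rasters, `imageId()` the
#' identifier and `leafTruth()` the attached ground truth (or `NULL`).
#' `trueRatio()` and `trueGrade()` read the ground-truth injury ratio and
#' grade label.
#'
#' @param object a [FluorescenceImage-class] or [LeafTruth-class].
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rgbImage", function(object) standardGeneric("rgbImage"))
#' @rdname accessors
#' @export
setGeneric("grayImage", function(object) standardGeneric("grayImage"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("leafTruth", function(object) standardGeneric("leafTruth"))
#' @rdname accessors
#' @export
setGeneric("trueRatio", function(object) standardGeneric("trueRatio"))
#' @rdname accessors
#' @export
setGeneric("trueGrade", function(object) standardGeneric("trueGrade"))

#' @rdname accessors
#' @export
setMethod("rgbImage", "FluorescenceImage", function(object) object@rgb)
#' @rdname accessors
#' @export
setMethod("grayImage", "FluorescenceImage", function(object) object@gray)
#' @rdname accessors
#' @export
setMethod("imageId", "FluorescenceImage", function(object) object@id)
#' @rdname accessors
#' @export
setMethod("leafTruth", "FluorescenceImage", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("trueRatio", "LeafTruth", function(object) object@lk_true)
#' @rdname accessors
#' @export
setMethod("trueGrade", "LeafTruth", function(object) object@grade_true)
#' @rdname accessors
#' @export
setMethod("trueRatio", "FluorescenceImage", function(object) {
  if (is.null(object@truth)) NA_real_ else object@truth@lk_true
})
#' @rdname accessors
#' @export
setMethod("trueGrade", "FluorescenceImage", function(object) {
  if (is.null(object@truth)) NA_character_ else object@truth@grade_true
})

setMethod("show", "FluorescenceImage", function(object) {
  d <- dim(object@gray)
  cat(sprintf("FluorescenceImage '%s': %d x %d\n", object@id, d[1], d[2]))
  if (!is.null(object@truth)) {
    cat(sprintf("  truth: lk = %.4f, grade = %s (%d leaf px, %d injured px)\n",
                object@truth@lk_true, object@truth@grade_true,
                sum(object@truth@leaf_mask), sum(object@truth@injury_mask)))
  } else {
    cat("  truth: <none>\n")
  }
  invisible(object)
})

setMethod("show", "LeafTruth", function(object) {
  cat(sprintf("LeafTruth: lk = %.4f, grade = %s\n",
              object@lk_true, object@grade_true))
  invisible(object)
})
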