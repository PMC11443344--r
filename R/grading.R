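#' Injury grade bands
#'
#' Chilling injury is graded from the injured-area ratio Lk (injured leaf
#' pixels / all leaf pixels) into four levels: sound (A), slight (B),
#' moderate (C) and severe (D). The bands are half-open, closed on the left:
#' \itemize{
#'   \item A (level 1): `0 <= Lk < 0.05`
#'   \item B (level 2): `0.05 <= Lk < 0.15`
#'   \item C (level 3): `0.15 <= Lk < 0.30`
#'   \item D (level 4): `0.30 <= Lk <= 1`
#' }
#' The published band edges leave exactly 5/15/30 percent unassigned ("<" on
#' one side, ">" on the other); closing on the left makes the mapping total
#' and deterministic, with 0.30 assigned to D.
#'
#' @param lk numeric vector of injury ratios in `[0, 1]`.
#' @return A data.frame with columns `label` (factor A-D) and `level`
#'   (integer 1-4), one row per input.
#' @examples
#' gradeFromRatio(c(0.04, 0.10, 0.29, 0.31))
#' @export
gradeFromRatio <- function(lk) {
  if (any(!is.finite(lk)) || any(lk < 0) || any(lk > 1))
    stop("lk must lie in [0, 1]")
  level <- findInterval(lk, c(0, 0.05, 0.15, 0.30))
  data.frame(
    label = factor(gradeLabels()[level], levels = gradeLabels()),
    level = as.integer(level)
  )
}

#' @rdname gradeFromRatio
#' @export
gradeLabels <- function() c("A", "B", "C", "D")

#' Injury-area ratio from masks
#'
#' Computes the injured-area ratio `Lk = N1 / N` where `N1` is the number of
#' injured pixels and `N` the number of leaf pixels. Pixel counts are exact
#' integers, so the ratio is exact at double precision.
#'
#' @param injury_mask logical matrix of injured pixels (subset of
#'   `leaf_mask`).
#' @param leaf_mask logical matrix of leaf pixels; must be non-empty.
#' @return A list of class `injury_measurement` with elements `n_injury`,
#'   `n_leaf`, `lk`, `grade` (factor label) and `level`.
#' @examples
#' leaf <- matrix(TRUE, 10, 10)
#' inj  <- leaf & FALSE; inj[1:3, 1:10] <- TRUE
#' injuryRatio(inj, leaf)
#' @export
injuryRatio <- function(injury_mask, leaf_mask) {
  stopifnot(is.logical(injury_mask), is.logical(leaf_mask),
            identical(dim(injury_mask), dim(leaf_mask)))
  if (!any(leaf_mask)) stop("leaf mask is empty")
  if (any(injury_mask & !leaf_mask))
    stop("injury mask must be a subset of the leaf mask")
  n1 <- sum(injury_mask)
  n  <- sum(leaf_mask)
  lk <- n1 / n
  g <- gradeFromRatio(lk)
  structure(
    list(n_injury = n1, n_leaf = n, lk = lk,
         grade = g$label, level = g$level),
    class = "injury_measurement"
  )
}

#' @export
print.injury_measurement <- function(x, ...) {
  cat(sprintf("Injury measurement: %d / %d leaf px, Lk = %.4f, grade %s (level %d)\n",
              x$n_injury, x$n_leaf, x$lk, as.character(x$grade), x$level))
  invisible(x)
}

#' Default segmentation bands
#'
#' HSV thresholds used by [segmentLeaf()] and [segmentInjury()]. The
#' fluorescence pseudo-color convention renders healthy leaf tissue red,
#' injured tissue yellow-green and background near-black, so plain HSV
#' thresholding separates the three. Thresholds are configuration, not
#' constants, so real instrument imagery can be re-tuned.
#'
#' @param v_background brightness (V, in `[0,1]`) at or below which a pixel
#'   is background.
#' @param injury_hue length-2 numeric; hue band (H in `[0,1]`) counted as
#'   injured (yellow-green).
#' @param min_component_frac connected components of the leaf mask smaller
#'   than this fraction of the image area are dropped as noise.
#' @return A named list of thresholds.
#' @export
segmentationBands <- function(v_background = 0.08,
                              injury_hue = c(0.16, 0.33),
                              min_component_frac = 0.001) {
  list(v_background = v_background,
       injury_hue = injury_hue,
       min_component_frac = min_component_frac)
}

# H, S, V planes (each H x W, in [0,1]) from the 0..255 rgb array
rgbToHsvPlanes <- function(rgb) {
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Segment the leaf from the background
#'
#' Thresholds brightness (HSV value) above the background level and keeps
#' connected components of at least `min_component_frac` of the image area
#' (8-connectivity), discarding isolated bright noise pixels.
#'
#' @param image a [FluorescenceImage-class].
#' @param bands thresholds from [segmentationBands()].
#' @return Logical leaf mask (`H x W`).
#' @export
segmentLeaf <- function(image, bands = segmentationBands()) {
  stopifnot(is(image, "FluorescenceImage"))
  v <- rgbToHsvPlanes(rgbImage(image))$v
  mask <- v > bands$v_background
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= max(1, bands$min_component_frac * length(mask)))
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("no leaf found")
  mask
}

#' Segment injured tissue within the leaf
#'
#' Marks leaf pixels whose hue falls inside the configured yellow-green
#' band. An empty injury mask (a sound leaf) is a valid result.
#'
#' @inheritParams segmentLeaf
#' @param leaf_mask logical leaf mask, e.g. from [segmentLeaf()];
#'   must be non-empty.
#' @return Logical injury mask, a subset of `leaf_mask`.
#' @export
segmentInjury <- function(image, leaf_mask, bands = segmentationBands()) {
  stopifnot(is(image, "FluorescenceImage"), is.logical(leaf_mask))
  if (!any(leaf_mask)) stop("leaf mask is empty")
  h <- rgbToHsvPlanes(rgbImage(image))$h
  leaf_mask & h >= bands$injury_hue[1] & h <= bands$injury_hue[2]
}

#' Grade a set of images by the segmentation pipeline
#'
#' Convenience wrapper: segment leaf and injury, measure the ratio, grade.
#'
#' @param images list of [FluorescenceImage-class] objects.
#' @param bands thresholds from [segmentationBands()].
#' @return data.frame with columns `id`, `n_leaf`, `n_injury`, `lk`,
#'   `grade`, `level`.
#' @export
gradeImages <- function(images, bands = segmentationBands()) {
  rows <- lapply(images, function(img) {
    leaf <- segmentLeaf(img, bands)
    inj <- segmentInjury(img, leaf, bands)
    m <- injuryRatio(inj, leaf)
    data.frame(id = imageId(img), n_leaf = m$n_leaf, n_injury = m$n_injury,
               lk = m$lk, grade = as.character(m$grade), level = m$level)
  })
  do.call(rbind, rows)
}
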