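#' Write a FluorescenceImage (and its masks) to PNG files
#'
#' Writes `<id>_rgb.png` (8-bit color), `<id>_gray.png` (8-bit single
#' channel) and, when ground truth is attached, `<id>_leaf.png` /
#' `<id>_injury.png` mask images.
#'
#' @param image a [FluorescenceImage-class].
#' @param dir output directory (created if needed).
#' @return The image id, invisibly.
#' @export
writeFluorescenceImage <- function(image, dir) {
  stopifnot(is(image, "FluorescenceImage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- imageId(image)
  png::writePNG(rgbImage(image) / 255, file.path(dir, paste0(id, "_rgb.png")))
  png::writePNG(grayImage(image) / 255, file.path(dir, paste0(id, "_gray.png")))
  tr <- leafTruth(image)
  if (!is.null(tr)) {
    png::writePNG(tr@leaf_mask * 1, file.path(dir, paste0(id, "_leaf.png")))
    png::writePNG(tr@injury_mask * 1, file.path(dir, paste0(id, "_injury.png")))
  }
  invisible(id)
}

#' Read a FluorescenceImage written by [writeFluorescenceImage()]
#'
#' Reads the RGB and gray PNG pair (gray is recomputed as the luminance
#' mean if only RGB exists) and re-attaches truth masks when present.
#'
#' @param dir directory containing the files.
#' @param id image identifier.
#' @return A [FluorescenceImage-class].
#' @export
readFluorescenceImage <- function(dir, id) {
  rgb_path <- file.path(dir, paste0(id, "_rgb.png"))
  if (!file.exists(rgb_path)) stop("missing image: ", rgb_path)
  rgb <- round(png::readPNG(rgb_path) * 255)
  if (length(dim(rgb)) == 3 && dim(rgb)[3] == 4) rgb <- rgb[, , 1:3]
  gray_path <- file.path(dir, paste0(id, "_gray.png"))
  gray <- if (file.exists(gray_path)) {
    g <- png::readPNG(gray_path)
    if (length(dim(g)) == 3) g <- g[, , 1]
    round(g * 255)
  } else round((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3)
  truth <- NULL
  leaf_path <- file.path(dir, paste0(id, "_leaf.png"))
  inj_path <- file.path(dir, paste0(id, "_injury.png"))
  if (file.exists(leaf_path) && file.exists(inj_path)) {
    rd <- function(p) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m > 0.5
    }
    leaf <- rd(leaf_path); inj <- rd(inj_path)
    lk <- sum(inj) / sum(leaf)
    truth <- new("LeafTruth", leaf_mask = leaf, injury_mask = inj,
                 lk_true = lk,
                 grade_true = as.character(gradeFromRatio(lk)$label))
  }
  FluorescenceImage(rgb, gray, id = id, truth = truth)
}

#' Write a dataset (images + manifest CSV) to a directory
#'
#' The manifest has columns `id`, `split`, `grade`, `lk_true`.
#'
#' @param dataset a [makeLeafDataset()] result.
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
writeLeafDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (img in c(dataset$train, dataset$test)) writeFluorescenceImage(img, dir)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(dataset$manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a dataset directory written by [writeLeafDataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return A list with `train`, `test` (image lists) and `manifest`.
#' @export
readLeafDataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  imgs <- lapply(manifest$id, function(id) readFluorescenceImage(dir, id))
  list(train = imgs[manifest$split == "train"],
       test = imgs[manifest$split == "test"],
       manifest = manifest)
}
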