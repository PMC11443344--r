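#' Canonical feature names and order
#'
#' `featureNames()` returns the fixed 36-name order of the full feature
#' vector: 18 color features (9 channel means, 9 ratios), 4 histogram
#' statistics, 6 GGCM features, 8 GLCM features. `selectedFeatureNames()`
#' returns the nine gray-image features that screen as very strongly
#' correlated with the injury grade (histogram mean/sd/skewness/smoothness,
#' low- and high-gradient advantage, gray and gradient distribution
#' non-uniformity, mean gradient) — the canonical classifier input set.
#'
#' @return Character vector of feature names.
#' @export
featureNames <- function() {
  c("R", "G", "B", "H", "S", "V", "L", "a", "b",
    "G_R", "G_B", "B_R", "S_H", "V_S", "V_H", "L_a", "L_b", "b_a",
    "hist_mean", "hist_sd", "hist_skew", "hist_smooth",
    "T1_low_grad", "T2_high_grad", "T3_gray_nonunif", "T4_grad_nonunif",
    "grad_mean", "grad_sd",
    "energy_mean", "entropy_mean", "inertia_mean", "corr_mean",
    "energy_sd", "entropy_sd", "inertia_sd", "corr_sd")
}

#' @rdname featureNames
#' @export
selectedFeatureNames <- function() {
  c("hist_mean", "hist_sd", "hist_skew", "hist_smooth",
    "T1_low_grad", "T2_high_grad", "T3_gray_nonunif", "T4_grad_nonunif",
    "grad_mean")
}

#' Feature-extraction configuration
#'
#' Quantization and co-occurrence settings for [extractFeatures()]. All are
#' implementation choices exposed as configuration: 16 gray and gradient
#' levels for the GGCM with threshold `Ns / 2`, 16 levels / distance 1 /
#' four symmetric directions for the GLCM (the four-direction aggregation
#' is what gives the energy/entropy/inertia/correlation standard-deviation
#' features).
#'
#' @param Ng,Ns,T GGCM gray levels, gradient levels and gradient threshold.
#' @param glcm_levels,glcm_distance GLCM quantization levels and offset.
#' @return Named list of settings.
#' @export
featureConfig <- function(Ng = 16L, Ns = 16L, T = Ns / 2,
                          glcm_levels = 16L, glcm_distance = 1L) {
  list(Ng = Ng, Ns = Ns, T = T,
       glcm_levels = glcm_levels, glcm_distance = glcm_distance)
}

#' Extract the full 36-feature vector for one image
#'
#' Concatenates [colorFeatures()] (18), [histogramFeatures()] (4),
#' [ggcmFeatures()] (6) and [glcmFeatures()] (8) in the order of
#' [featureNames()]. Deterministic in its inputs.
#'
#' @param image a [FluorescenceImage-class].
#' @param leaf_mask logical leaf mask; defaults to [segmentLeaf()] output.
#' @param config settings from [featureConfig()].
#' @return Named numeric vector of length 36.
#' @export
extractFeatures <- function(image, leaf_mask = segmentLeaf(image),
                            config = featureConfig()) {
  stopifnot(is(image, "FluorescenceImage"))
  gray <- grayImage(image)
  v <- c(colorFeatures(rgbImage(image), leaf_mask),
         histogramFeatures(gray, leaf_mask),
         ggcmFeatures(buildGGCM(gray, leaf_mask, config$Ng, config$Ns,
                                config$T)),
         glcmFeatures(buildGLCM(gray, leaf_mask, config$glcm_levels,
                                config$glcm_distance)))
  stopifnot(identical(names(v), featureNames()))
  v
}

#' Feature table for a set of images
#'
#' Runs the segmentation and feature extraction over a list of images and
#' returns one row per image, with the ground-truth grade when present.
#'
#' @param images list of [FluorescenceImage-class] objects.
#' @param config settings from [featureConfig()].
#' @param bands segmentation thresholds from [segmentationBands()].
#' @return data.frame: `id`, `grade` (NA when no truth), then the 36
#'   feature columns in [featureNames()] order.
#' @export
buildFeatureTable <- function(images, config = featureConfig(),
                              bands = segmentationBands()) {
  rows <- lapply(images, function(img) {
    mask <- segmentLeaf(img, bands)
    f <- extractFeatures(img, mask, config)
    cbind(data.frame(id = imageId(img), grade = trueGrade(img)),
          as.data.frame(t(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a feature table CSV
#'
#' The CSV carries the fixed 36-column feature header (plus `id` and
#' `grade`), matching [featureNames()] order.
#'
#' @param features data.frame from [buildFeatureTable()].
#' @param path file path.
#' @return `readFeatureCSV()` returns the data.frame; `writeFeatureCSV()`
#'   returns `path` invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  stopifnot(all(featureNames() %in% names(features)))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(featureNames() %in% names(out)))
    stop("not a feature table: missing feature columns")
  out
}
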