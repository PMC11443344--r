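#' Generate a synthetic fluorescence leaf image with ground truth
#'
#' Emulates the pseudo-color convention of fluorescence imagers on
#' cold-stressed tomato leaves: healthy tissue renders red, injured
#' (chilling-damaged) tissue yellow-green, background near-black; the paired
#' grayscale raster is the underlying "fluorescence yield" field, depressed
#' inside injured tissue (healthy about 180, injured about 90, background 0,
#' each +/- Gaussian noise). The leaf is a union of 1-3 random ellipses;
#' injury grows as random disks accreted inside the leaf and trimmed at the
#' blob boundary until the injured-pixel count matches
#' `round(target_lk * n_leaf)` exactly, so the realized ratio is within one
#' pixel of the target (well inside +/- 0.02 for any leaf of 25+ pixels).
#'
#' Hues are drawn inside guard bands (healthy H in `[0.96, 1.05] mod 1`,
#' injured H in `[0.17, 0.32]`) strictly inside the default segmentation
#' bands of [segmentationBands()]; 8-bit quantization keeps realized hues
#' inside those bands for `noise_sd <= 12` (the documented cap), so the red
#' and yellow-green bands never overlap.
#'
#' @param seed integer seed; the image is a deterministic function of it.
#' @param target_lk requested injured-area ratio in `[0, 0.8]`.
#' @param size integer `c(H, W)`, at least 32 x 32.
#' @param noise_sd standard deviation (gray levels) of the fluorescence
#'   noise; background receives `noise_sd / 4`.
#' @param id identifier stored in the image.
#' @return A [FluorescenceImage-class] with a [LeafTruth-class] attached.
#' @examples
#' img <- makeLeafImage(seed = 7, target_lk = 0.35)
#' trueGrade(img)
#' @export
makeLeafImage <- function(seed, target_lk, size = c(96L, 96L), noise_sd = 4,
                          id = sprintf("leaf_s%d", seed)) {
  stopifnot(target_lk >= 0, target_lk <= 0.8, noise_sd >= 0)
  size <- as.integer(size)
  if (any(size < 32L)) stop("size must be at least 32 x 32")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  H <- size[1]; W <- size[2]

  leaf <- drawLeafMask(H, W)
  n_leaf <- sum(leaf)
  n_target <- round(target_lk * n_leaf)
  injury <- accreteInjury(leaf, n_target, target_lk)

  lk_true <- sum(injury) / n_leaf
  grade_true <- as.character(gradeFromRatio(lk_true)$label)

  # fluorescence yield field: healthy bright, injured depressed, bg ~ 0
  yield <- matrix(0, H, W)
  yield[leaf] <- 180 + stats::rnorm(n_leaf, sd = noise_sd)
  yield[injury] <- 90 + stats::rnorm(sum(injury), sd = noise_sd)
  yield[leaf] <- clip(yield[leaf], 30, 255)  # leaf stays above background V
  bg <- !leaf
  yield[bg] <- clip(abs(stats::rnorm(sum(bg), sd = noise_sd / 4)), 0, 15)
  gray <- round(yield)

  hplane <- matrix(0, H, W)
  hplane[leaf] <- stats::runif(n_leaf, 0.96, 1.05) %% 1
  hplane[injury] <- stats::runif(sum(injury), 0.17, 0.32)
  splane <- matrix(0, H, W)
  splane[leaf] <- stats::runif(n_leaf, 0.75, 1)
  vplane <- yield / 255

  rgb <- hsvToRgbArray(hplane, splane, vplane)
  for (ch in 1:3) {  # achromatic background: r = g = b = gray
    plane <- rgb[, , ch]; plane[bg] <- gray[bg]; rgb[, , ch] <- plane
  }

  truth <- new("LeafTruth", leaf_mask = leaf, injury_mask = injury,
               lk_true = lk_true, grade_true = grade_true)
  FluorescenceImage(rgb, gray, id = id, truth = truth)
}

# union of 1-3 random ellipses roughly centered, guaranteed non-trivial area
drawLeafMask <- function(H, W) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  n_ell <- sample(1:3, 1)
  mask <- matrix(FALSE, H, W)
  for (e in seq_len(n_ell)) {
    cy <- H * stats::runif(1, 0.4, 0.6); cx <- W * stats::runif(1, 0.4, 0.6)
    a <- stats::runif(1, 0.20, 0.34) * W; b <- stats::runif(1, 0.20, 0.34) * H
    th <- stats::runif(1, 0, pi)
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  mask
}

# grow random disks inside the leaf, then trim boundary pixels until the
# injured count equals n_target exactly
accreteInjury <- function(leaf, n_target, target_lk, max_iter = 500L) {
  H <- nrow(leaf); W <- ncol(leaf)
  injury <- matrix(FALSE, H, W)
  if (n_target == 0) return(injury)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  leaf_idx <- which(leaf)
  it <- 0L
  while (sum(injury) < n_target) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf("unreachable target ratio %.3f: achieved %.3f",
                   target_lk, sum(injury) / length(leaf_idx)))
    ctr <- leaf_idx[sample.int(length(leaf_idx), 1)]
    cy <- (ctr - 1) %% H + 1; cx <- (ctr - 1) %/% H + 1
    deficit <- n_target - sum(injury)
    r <- clip(sqrt(deficit / pi) * stats::runif(1, 0.6, 1.1), 1.5, 0.3 * min(H, W))
    disk <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    injury <- injury | (disk & leaf)
  }
  while (sum(injury) > n_target) {
    boundary <- which(injuryBoundary(injury))
    excess <- sum(injury) - n_target
    drop <- if (length(boundary) <= excess) boundary else
      boundary[sample.int(length(boundary), excess)]
    injury[drop] <- FALSE
  }
  injury
}

# injured pixels with at least one non-injured 4-neighbour (or on the border)
injuryBoundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !nb
}

# vectorized HSV -> 8-bit RGB array via the grDevices hex path
hsvToRgbArray <- function(h, s, v) {
  d <- dim(h)
  hex <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(clip(v, 0, 1)))
  m <- grDevices::col2rgb(hex)
  arr <- array(0L, c(d, 3L))
  arr[, , 1] <- matrix(as.integer(m[1, ]), d[1], d[2])
  arr[, , 2] <- matrix(as.integer(m[2, ]), d[1], d[2])
  arr[, , 3] <- matrix(as.integer(m[3, ]), d[1], d[2])
  arr
}

#' Generate a labelled synthetic train/test image set
#'
#' Draws, per grade, target injury ratios uniformly inside that grade's band
#' (at least 0.005 away from the band edges; grade D is capped at the
#' generator's 0.8 ratio ceiling) and renders one image per draw. The default
#' counts are 42/46/46/42 training and 10/12/12/10 test images for grades
#' A-D (176 + 44 images).
#'
#' @param seed integer seed for the whole collection.
#' @param train_counts,test_counts integer vectors of length 4 (grades
#'   A, B, C, D), each count at least 1.
#' @param size,noise_sd passed to [makeLeafImage()].
#' @return A list with elements `train` and `test` (lists of
#'   [FluorescenceImage-class]) and `manifest` (data.frame with `id`,
#'   `split`, `grade`, `lk_true`).
#' @export
makeLeafDataset <- function(seed, train_counts = c(42L, 46L, 46L, 42L),
                            test_counts = c(10L, 12L, 12L, 10L),
                            size = c(96L, 96L), noise_sd = 4) {
  stopifnot(length(train_counts) == 4, length(test_counts) == 4,
            all(train_counts >= 1), all(test_counts >= 1))
  bands <- list(A = c(0.005, 0.045), B = c(0.055, 0.145),
                C = c(0.155, 0.295), D = c(0.305, 0.795))
  out <- list(train = list(), test = list())
  manifest <- NULL
  k <- 0L
  for (split in c("train", "test")) {
    counts <- if (split == "train") train_counts else test_counts
    for (g in 1:4) {
      lab <- gradeLabels()[g]
      set.seed(childSeed(seed, 100L * g + (split == "test")))
      targets <- stats::runif(counts[g], bands[[lab]][1], bands[[lab]][2])
      for (j in seq_len(counts[g])) {
        k <- k + 1L
        id <- sprintf("%s_%s_%03d", split, lab, j)
        img <- makeLeafImage(childSeed(seed, 1000L + k), targets[j],
                             size = size, noise_sd = noise_sd, id = id)
        out[[split]][[length(out[[split]]) + 1L]] <- img
        manifest <- rbind(manifest, data.frame(
          id = id, split = split, grade = trueGrade(img),
          lk_true = trueRatio(img)))
      }
    }
  }
  out$manifest <- manifest
  out
}

#' Generate a synthetic table of the nine screened features
#'
#' A fast stand-in for the imaging chain when exercising the classifier:
#' rows are drawn from four class-conditional Gaussians (unit variance)
#' whose means move monotonically with the grade level, in the direction
#' each of the nine screened gray-image features responds to injury
#' (histogram mean/sd/skewness/smoothness and high-gradient advantage and
#' mean gradient rise in magnitude with damage contrast; low-gradient
#' advantage and the two non-uniformities fall). `class_separation = 0`
#' makes all four class distributions identical (no signal).
#'
#' @param seed integer seed.
#' @param n_per_class samples per grade (at least 2).
#' @param class_separation mean shift between adjacent grades, in sd units.
#' @return data.frame with a `grade` factor and nine numeric feature
#'   columns named after the screened features.
#' @export
makeFeatureTable <- function(seed, n_per_class, class_separation) {
  stopifnot(n_per_class >= 2, class_separation >= 0)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  feats <- selectedFeatureNames()
  dir <- c(1, 1, 1, 1, -1, 1, -1, -1, 1)
  rows <- lapply(1:4, function(g) {
    mu <- (g - 2.5) * class_separation * dir
    x <- matrix(stats::rnorm(n_per_class * 9), n_per_class, 9)
    x <- sweep(x, 2, mu, `+`)
    colnames(x) <- feats
    cbind(data.frame(grade = gradeLabels()[g]), as.data.frame(x))
  })
  out <- do.call(rbind, rows)
  out$grade <- factor(out$grade, levels = gradeLabels())
  rownames(out) <- NULL
  out
}
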