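#' Histogram statistics of the gray image over the leaf mask
#'
#' With `H(i)` the normalized histogram of the leaf-pixel gray levels `i`
#' (0-255):
#' \itemize{
#'   \item mean `E = sum(i * H(i))` — overall brightness;
#'   \item standard deviation `sigma = sqrt(sum((i - E)^2 * H(i)))` —
#'     spread about the mean;
#'   \item skewness (third moment) `S = cbrt(sum((i - E)^3 * H(i)))` —
#'     asymmetry of the gray distribution, on the gray-level scale;
#'   \item smoothness `R = 1 - 1 / (1 + sigma_n^2)` with `sigma_n =
#'     sigma / 255`, so `R` lies in `[0, 1)` instead of saturating at 1.
#' }
#' These are histogram-weighted central moments (equivalently pixelwise
#' moments over the mask).
#'
#' @param gray integer `H x W` matrix in `[0, 255]`.
#' @param leaf_mask logical mask; must be non-empty.
#' @return Named numeric vector `hist_mean`, `hist_sd`, `hist_skew`,
#'   `hist_smooth`.
#' @export
histogramFeatures <- function(gray, leaf_mask) {
  stopifnot(is.matrix(gray), is.logical(leaf_mask))
  if (!any(leaf_mask)) stop("leaf mask is empty")
  x <- as.numeric(gray[leaf_mask])
  E <- mean(x)
  v <- mean((x - E)^2)
  m3 <- mean((x - E)^3)
  s <- sqrt(v)
  sn <- s / 255
  c(hist_mean = E,
    hist_sd = s,
    hist_skew = sign(m3) * abs(m3)^(1 / 3),
    hist_smooth = 1 - 1 / (1 + sn^2))
}

# 3x3 Sobel gradient magnitude with replicate padding at the borders
sobelMagnitude <- function(gray) {
  g <- apply(gray, 2, as.numeric)
  H <- nrow(g); W <- ncol(g)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- g
  pad[1, ] <- pad[2, ]; pad[H + 2, ] <- pad[H + 1, ]
  pad[, 1] <- pad[, 2]; pad[, W + 2] <- pad[, W + 1]
  sh <- function(dr, dc) pad[(1 + dr):(H + dr), (1 + dc):(W + dc)]
  # gx: horizontal (column) derivative; gy: vertical (row) derivative
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  sqrt(gx^2 + gy^2)
}

# uniform quantization of values in [0, 255] into 1..levels
quantizeGray <- function(g, levels) {
  pmin(floor(as.numeric(g) * levels / 256), levels - 1) + 1L
}

#' Build the gray-gradient co-occurrence matrix (GGCM)
#'
#' Joint histogram `H(i, j)` of quantized gray level `i` (uniform over
#' 0-255 into `Ng` bins) and quantized 3x3-Sobel gradient magnitude `j`
#' (uniform over the observed maximum within the mask into `Ns` bins),
#' counted over leaf pixels. `P = H / sum(H)` is the normalized matrix and
#' `T` the gradient threshold separating "low" from "high" gradients.
#'
#' @param gray integer `H x W` matrix in `[0, 255]`.
#' @param leaf_mask logical mask with at least 9 pixels (3x3 support).
#' @param Ng,Ns numbers of gray and gradient levels (at least 2).
#' @param T gradient threshold, `1 <= T < Ns`; defaults to `Ns / 2`
#'   (midpoint split, the quantization itself being unspecified upstream).
#' @return List of class `ggcm` with `counts` (`Ng x Ns`), `total`, `P`,
#'   `T`, `Ng`, `Ns`.
#' @export
buildGGCM <- function(gray, leaf_mask, Ng = 16L, Ns = 16L, T = Ns / 2) {
  stopifnot(Ng >= 2, Ns >= 2, T >= 1, T < Ns)
  if (sum(leaf_mask) < 9) stop("mask smaller than the 3x3 gradient support")
  grad <- sobelMagnitude(gray)
  gi <- quantizeGray(gray[leaf_mask], Ng)
  gm <- grad[leaf_mask]
  mx <- max(gm)
  gj <- if (mx == 0) rep(1L, length(gm)) else
    pmin(floor(gm * Ns / mx), Ns - 1) + 1L
  counts <- matrix(0, Ng, Ns)
  tab <- table(factor(gi, levels = 1:Ng), factor(gj, levels = 1:Ns))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts, total = sum(counts),
                 P = counts / sum(counts), T = T, Ng = Ng, Ns = Ns),
            class = "ggcm")
}

#' GGCM texture features
#'
#' From a [buildGGCM()] matrix with counts `H(i, j)`, total `H`, normalized
#' `P(i, j)` and gradient threshold `T`:
#' \itemize{
#'   \item low-gradient advantage
#'     `T1 = sum_i sum_{j <= T} H(i, j) / H` — dominance of flat regions;
#'   \item high-gradient advantage
#'     `T2 = sum_i sum_{j > T} j^2 H(i, j) / H` — weight of sharp edges;
#'   \item gray-distribution non-uniformity
#'     `T3 = sum_i (sum_j H(i, j))^2 / H`;
#'   \item gradient-distribution non-uniformity
#'     `T4 = sum_j (sum_i H(i, j))^2 / H`;
#'   \item mean gradient `mu = sum_j j * p(j)` and gradient standard
#'     deviation `sd = sqrt(sum_j (j - mu)^2 p(j))` with marginal
#'     `p(j) = sum_i P(i, j)`.
#' }
#'
#' @param G a `ggcm` object from [buildGGCM()].
#' @return Named numeric vector `T1_low_grad`, `T2_high_grad`,
#'   `T3_gray_nonunif`, `T4_grad_nonunif`, `grad_mean`, `grad_sd`.
#' @export
ggcmFeatures <- function(G) {
  stopifnot(inherits(G, "ggcm"))
  if (G$total == 0) stop("empty GGCM")
  Hm <- G$counts; tot <- G$total
  j <- seq_len(G$Ns)
  low <- j <= G$T
  pj <- colSums(G$P)
  mu <- sum(j * pj)
  c(T1_low_grad = sum(Hm[, low]) / tot,
    T2_high_grad = sum(sweep(Hm[, !low, drop = FALSE], 2, j[!low]^2, `*`)) / tot,
    T3_gray_nonunif = sum(rowSums(Hm)^2) / tot,
    T4_grad_nonunif = sum(colSums(Hm)^2) / tot,
    grad_mean = mu,
    grad_sd = sqrt(sum((j - mu)^2 * pj)))
}

#' Build gray-level co-occurrence matrices (GLCM) in four directions
#'
#' For each direction (0, 45, 90, 135 degrees) at the given pixel distance,
#' counts symmetric co-occurring quantized gray-level pairs where both
#' pixels lie inside the mask, normalizes to `Q`, and records the marginal
#' means and standard deviations used by the correlation feature.
#'
#' @param gray integer `H x W` matrix in `[0, 255]`.
#' @param leaf_mask logical mask.
#' @param levels number of gray levels (uniform quantization of 0-255).
#' @param distance pixel offset (at least 1).
#' @return List of class `glcm_set`: four `glcm` elements (named `d0`,
#'   `d45`, `d90`, `d135`), each with `Q`, `mu_x`, `mu_y`, `sigma_x`,
#'   `sigma_y`, `levels`.
#' @export
buildGLCM <- function(gray, leaf_mask, levels = 16L, distance = 1L) {
  stopifnot(levels >= 2, distance >= 1)
  H <- nrow(gray); W <- ncol(gray)
  q <- matrix(quantizeGray(gray, levels), H, W)
  d <- as.integer(distance)
  # offsets in (row, col); rows grow downward so 45 deg pairs up-right
  offs <- list(d0 = c(0L, d), d45 = c(-d, d), d90 = c(-d, 0L), d135 = c(-d, -d))
  out <- lapply(offs, function(o) {
    r0 <- max(1L, 1L - o[1]):min(H, H - o[1])
    c0 <- max(1L, 1L - o[2]):min(W, W - o[2])
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + o[1], c0 + o[2], drop = FALSE]
    ok <- leaf_mask[r0, c0, drop = FALSE] &
          leaf_mask[r0 + o[1], c0 + o[2], drop = FALSE]
    if (!any(ok)) stop("no valid pixel pairs inside the mask")
    counts <- matrix(0, levels, levels)
    tab <- table(factor(a[ok], levels = 1:levels),
                 factor(b[ok], levels = 1:levels))
    counts[] <- as.numeric(tab)
    counts <- counts + t(counts)  # symmetric accumulation
    Q <- counts / sum(counts)
    px <- rowSums(Q); py <- colSums(Q)
    i <- seq_len(levels)
    mu_x <- sum(i * px); mu_y <- sum(i * py)
    structure(list(Q = Q, mu_x = mu_x, mu_y = mu_y,
                   sigma_x = sqrt(sum((i - mu_x)^2 * px)),
                   sigma_y = sqrt(sum((i - mu_y)^2 * py)),
                   levels = levels),
              class = "glcm")
  })
  structure(out, class = "glcm_set")
}

# per-direction GLCM scalars
glcmScalars <- function(g) {
  Q <- g$Q
  i <- seq_len(g$levels)
  ij <- outer(i, i)
  dif2 <- outer(i, i, function(a, b) (a - b)^2)
  pos <- Q > 0
  ent <- -sum(Q[pos] * log(Q[pos]))
  cor <- if (g$sigma_x * g$sigma_y == 0) 0 else
    (sum(ij * Q) - g$mu_x * g$mu_y) / (g$sigma_x * g$sigma_y)
  c(energy = sum(Q^2), entropy = ent, inertia = sum(dif2 * Q), corr = cor)
}

#' GLCM texture features aggregated over directions
#'
#' Per direction: energy (angular second moment) `ASM = sum Q^2`, entropy
#' `ENT = -sum Q log Q` over positive cells (natural log; the conventional
#' leading minus makes entropy non-negative), inertia (contrast)
#' `INE = sum (i - j)^2 Q`, and correlation
#' `COR = (sum i j Q - mu_x mu_y) / (sigma_x sigma_y)` (0 when a marginal is
#' degenerate). Each is then summarized by the mean and the population
#' standard deviation across the four directions.
#'
#' @param glcms a `glcm_set` from [buildGLCM()].
#' @return Named numeric vector of 8 values: `energy_mean`, `entropy_mean`,
#'   `inertia_mean`, `corr_mean`, `energy_sd`, `entropy_sd`, `inertia_sd`,
#'   `corr_sd`.
#' @export
glcmFeatures <- function(glcms) {
  stopifnot(inherits(glcms, "glcm_set"))
  vals <- sapply(glcms, glcmScalars)  # 4 stats x 4 directions
  mn <- rowMeans(vals)
  sd4 <- sqrt(rowMeans((vals - mn)^2))  # population sd over directions
  c(energy_mean = mn[["energy"]], entropy_mean = mn[["entropy"]],
    inertia_mean = mn[["inertia"]], corr_mean = mn[["corr"]],
    energy_sd = sd4[["energy"]], entropy_sd = sd4[["entropy"]],
    inertia_sd = sd4[["inertia"]], corr_sd = sd4[["corr"]])
}
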