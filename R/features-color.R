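#' Standard sRGB to CIELAB (D65) conversion
#'
#' Implements the canonical conversion chain: IEC 61966-2-1 sRGB
#' electro-optical transfer (piecewise gamma), the standard sRGB-to-XYZ
#' matrix, and CIE L*a*b* with the D65 reference white
#' `(0.95047, 1, 1.08883)`. Implemented directly because the conversions
#' shipped with base graphics use slightly different internal constants and
#' disagree with the textbook chain at the 1e-1 to 1e-3 level.
#'
#' @param rgb numeric matrix `n x 3` with values in `[0, 1]`.
#' @return numeric matrix `n x 3` with columns `L` (0-100), `a`, `b`.
#' @export
srgbToLab <- function(rgb) {
  stopifnot(is.matrix(rgb), ncol(rgb) == 3)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wn <- c(0.95047, 1, 1.08883)
  r <- sweep(xyz, 2, wn, `/`)
  eps <- (6 / 29)^3
  f <- ifelse(r > eps, r^(1 / 3), r / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Color descriptor features over the leaf mask
#'
#' The 18 color-image features: nine color descriptors — the per-pixel
#' channel means of R, G, B (0-255), H, S, V (0-1, from the standard HSV
#' model) and L, a, b (CIELAB, D65) over leaf pixels — and nine ratios of
#' those means: G/R, G/B, B/R, S/H, V/S, V/H, L/a, L/b, b/a.
#'
#' Ratios use a sign-preserving epsilon guard, `x / (sign(y) * max(|y|,
#' 1e-9))`, because achromatic leaves drive S, H, a or b towards zero.
#'
#' @param rgb integer `H x W x 3` array in `[0, 255]`.
#' @param leaf_mask logical `H x W` mask; must be non-empty.
#' @return Named numeric vector of length 18.
#' @export
colorFeatures <- function(rgb, leaf_mask) {
  stopifnot(length(dim(rgb)) == 3, is.logical(leaf_mask))
  if (!any(leaf_mask)) stop("leaf mask is empty")
  r <- rgb[, , 1][leaf_mask]; g <- rgb[, , 2][leaf_mask]; b <- rgb[, , 3][leaf_mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  lab <- srgbToLab(cbind(r, g, b) / 255)
  m <- c(R = mean(r), G = mean(g), B = mean(b),
         H = mean(hsv[1, ]), S = mean(hsv[2, ]), V = mean(hsv[3, ]),
         L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]))
  ratios <- c(
    G_R = guardedRatio(m[["G"]], m[["R"]]),
    G_B = guardedRatio(m[["G"]], m[["B"]]),
    B_R = guardedRatio(m[["B"]], m[["R"]]),
    S_H = guardedRatio(m[["S"]], m[["H"]]),
    V_S = guardedRatio(m[["V"]], m[["S"]]),
    V_H = guardedRatio(m[["V"]], m[["H"]]),
    L_a = guardedRatio(m[["L"]], m[["a"]]),
    L_b = guardedRatio(m[["L"]], m[["b"]]),
    b_a = guardedRatio(m[["b"]], m[["a"]])
  )
  c(m, ratios)
}
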