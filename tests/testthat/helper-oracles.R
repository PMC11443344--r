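# Independent brute-force oracles, deliberately written as scalar loops so
# they share no code path with the vectorized implementations they check.

# per-pixel HSV via the hexagonal model
oracle_hsv <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b)
  v <- mx
  s <- if (mx == 0) 0 else (mx - mn) / mx
  h <- if (mx == mn) 0 else if (mx == r) ((g - b) / (mx - mn)) %% 6
       else if (mx == g) (b - r) / (mx - mn) + 2
       else (r - g) / (mx - mn) + 4
  c(h = h / 6, s = s, v = v)
}

# per-pixel sRGB -> CIELAB (D65), scalar arithmetic
oracle_lab <- function(r, g, b) {
  f_inv <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  rl <- f_inv(r / 255); gl <- f_inv(g / 255); bl <- f_inv(b / 255)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  fl <- function(u) if (u > (6 / 29)^3) u^(1 / 3) else u / (3 * (6 / 29)^2) + 4 / 29
  fx <- fl(x / 0.95047); fy <- fl(y / 1); fz <- fl(z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# pixelwise histogram moments over a mask
oracle_hist <- function(gray, mask) {
  xs <- c()
  for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray)))
    if (mask[i, j]) xs <- c(xs, gray[i, j])
  E <- sum(xs) / length(xs)
  v <- sum((xs - E)^2) / length(xs)
  m3 <- sum((xs - E)^3) / length(xs)
  c(E = E, sd = sqrt(v), skew = sign(m3) * abs(m3)^(1 / 3),
    smooth = 1 - 1 / (1 + (sqrt(v) / 255)^2))
}

# Sobel magnitude by explicit kernel loop with replicate padding
oracle_sobel <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  at <- function(i, j) gray[min(max(i, 1), H), min(max(j, 1), W)]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      gx <- gx + kx[di + 2, dj + 2] * at(i + di, j + dj)
      gy <- gy + ky[di + 2, dj + 2] * at(i + di, j + dj)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_quant <- function(x, levels) min(floor(x * levels / 256), levels - 1) + 1

# full GGCM by loops: counts, normalized P, and the six features by direct
# summation of their defining formulas
oracle_ggcm <- function(gray, mask, Ng, Ns, T) {
  grad <- oracle_sobel(gray)
  gmax <- 0
  for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray)))
    if (mask[i, j] && grad[i, j] > gmax) gmax <- grad[i, j]
  H <- matrix(0, Ng, Ns)
  for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray))) {
    if (!mask[i, j]) next
    gi <- oracle_quant(gray[i, j], Ng)
    gj <- if (gmax == 0) 1 else min(floor(grad[i, j] * Ns / gmax), Ns - 1) + 1
    H[gi, gj] <- H[gi, gj] + 1
  }
  tot <- sum(H)
  P <- H / tot
  T1 <- 0; T2 <- 0
  for (i in 1:Ng) for (j in 1:Ns) {
    if (j <= T) T1 <- T1 + H[i, j] else T2 <- T2 + j^2 * H[i, j]
  }
  T1 <- T1 / tot; T2 <- T2 / tot
  T3 <- 0
  for (i in 1:Ng) T3 <- T3 + sum(H[i, ])^2
  T3 <- T3 / tot
  T4 <- 0
  for (j in 1:Ns) T4 <- T4 + sum(H[, j])^2
  T4 <- T4 / tot
  mu <- 0
  for (j in 1:Ns) mu <- mu + j * sum(P[, j])
  sdv <- 0
  for (j in 1:Ns) sdv <- sdv + (j - mu)^2 * sum(P[, j])
  list(counts = H, P = P,
       features = c(T1 = T1, T2 = T2, T3 = T3, T4 = T4,
                    mu = mu, sd = sqrt(sdv)))
}

# GLCM for one (dr, dc) offset by looping every pixel pair (symmetric)
oracle_glcm <- function(gray, mask, levels, dr, dc) {
  H <- nrow(gray); W <- ncol(gray)
  counts <- matrix(0, levels, levels)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 < 1 || i2 > H || j2 < 1 || j2 > W) next
    if (!mask[i, j] || !mask[i2, j2]) next
    a <- oracle_quant(gray[i, j], levels)
    b <- oracle_quant(gray[i2, j2], levels)
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  counts / sum(counts)
}

# GLCM scalars by direct summation over a normalized matrix
oracle_glcm_scalars <- function(Q) {
  lev <- nrow(Q)
  asm <- 0; ent <- 0; ine <- 0; sij <- 0
  px <- rowSums(Q); py <- colSums(Q)
  mux <- sum((1:lev) * px); muy <- sum((1:lev) * py)
  sx <- sqrt(sum(((1:lev) - mux)^2 * px))
  sy <- sqrt(sum(((1:lev) - muy)^2 * py))
  for (i in 1:lev) for (j in 1:lev) {
    asm <- asm + Q[i, j]^2
    if (Q[i, j] > 0) ent <- ent - Q[i, j] * log(Q[i, j])
    ine <- ine + (i - j)^2 * Q[i, j]
    sij <- sij + i * j * Q[i, j]
  }
  cor <- if (sx * sy == 0) 0 else (sij - mux * muy) / (sx * sy)
  c(energy = asm, entropy = ent, inertia = ine, corr = cor)
}

# Spearman via independent ranking + Pearson (stats::cor on ranks)
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# confusion tally by explicit loop
oracle_confusion <- function(y_true, y_pred, labels = c("A", "B", "C", "D")) {
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(actual = labels, predicted = labels))
  for (k in seq_along(y_true))
    m[y_true[k], y_pred[k]] <- m[y_true[k], y_pred[k]] + 1L
  m
}
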