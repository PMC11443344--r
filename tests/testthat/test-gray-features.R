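test_that("histogram statistics handle degenerate and two-point cases", {
  mask <- matrix(TRUE, 16, 16)
  const <- matrix(37L, 16, 16)
  h <- histogramFeatures(const, mask)
  expect_equal(unname(h), c(37, 0, 0, 0))

  two <- matrix(c(0L, 255L), 16, 16)  # half 0, half 255
  h2 <- histogramFeatures(two, mask)
  expect_equal(h2[["hist_mean"]], 127.5)
  expect_equal(h2[["hist_sd"]], 127.5)
  expect_equal(h2[["hist_skew"]], 0)
  expect_error(histogramFeatures(const, matrix(FALSE, 16, 16)), "empty")
})

test_that("histogram statistics equal brute-force pixelwise moments", {
  for (s in c(1, 2, 3)) {
    rg <- random_gray(s, n = 10, p_mask = 0.7)
    rg$mask[1] <- TRUE
    got <- histogramFeatures(rg$gray, rg$mask)
    want <- oracle_hist(rg$gray, rg$mask)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("GGCM of a constant image concentrates in the lowest gradient bin", {
  mask <- matrix(TRUE, 16, 16)
  G <- buildGGCM(matrix(120L, 16, 16), mask, Ng = 8, Ns = 8, T = 4)
  expect_equal(sum(G$P), 1)
  expect_equal(sum(G$counts[, 1]), G$total)
  f <- ggcmFeatures(G)
  expect_equal(f[["T1_low_grad"]], 1)
  expect_equal(f[["T2_high_grad"]], 0)
  expect_equal(f[["grad_sd"]], 0)
})

test_that("GGCM counts and features match exhaustive enumeration", {
  for (s in c(4, 5, 6)) {
    rg <- random_gray(s, n = 8, p_mask = 0.85)
    rg$mask[1:4, 1:4] <- TRUE
    G <- buildGGCM(rg$gray, rg$mask, Ng = 4, Ns = 4, T = 2)
    want <- oracle_ggcm(rg$gray, rg$mask, Ng = 4, Ns = 4, T = 2)
    expect_equal(G$counts, want$counts)
    expect_equal(sum(G$P), 1, tolerance = 1e-12)
    got <- ggcmFeatures(G)
    expect_equal(unname(got), unname(want$features), tolerance = 1e-9)
  }
})

test_that("all GGCM mass on one cell makes both non-uniformities equal the total", {
  counts <- matrix(0, 4, 4); counts[2, 3] <- 17
  G <- structure(list(counts = counts, total = 17, P = counts / 17,
                      T = 2, Ng = 4, Ns = 4), class = "ggcm")
  f <- ggcmFeatures(G)
  expect_equal(f[["T3_gray_nonunif"]], 17)
  expect_equal(f[["T4_grad_nonunif"]], 17)
})

test_that("tiny masks are rejected by the gradient support check", {
  m <- matrix(FALSE, 16, 16); m[1:2, 1:2] <- TRUE
  expect_error(buildGGCM(matrix(0L, 16, 16), m), "3x3")
})

test_that("GLCM of a constant image is a single unit cell", {
  mask <- matrix(TRUE, 16, 16)
  gl <- buildGLCM(matrix(200L, 16, 16), mask, levels = 8)
  for (g in gl) {
    expect_equal(sum(g$Q), 1, tolerance = 1e-12)
    expect_equal(sum(g$Q > 0), 1)
  }
  f <- glcmFeatures(gl)
  expect_equal(f[["energy_mean"]], 1)
  expect_equal(f[["entropy_mean"]], 0)
  expect_equal(f[["inertia_mean"]], 0)
  expect_equal(f[["corr_mean"]], 0)  # degenerate-marginal convention
  expect_equal(f[["energy_sd"]], 0)
})

test_that("GLCM matrices are symmetric, normalized and match pair enumeration", {
  offs <- list(d0 = c(0, 1), d45 = c(-1, 1), d90 = c(-1, 0), d135 = c(-1, -1))
  for (s in c(7, 8)) {
    rg <- random_gray(s, n = 8, p_mask = 0.8)
    rg$mask[3:6, 3:6] <- TRUE
    gl <- buildGLCM(rg$gray, rg$mask, levels = 4, distance = 1)
    for (nm in names(offs)) {
      Q <- gl[[nm]]$Q
      expect_equal(sum(Q), 1, tolerance = 1e-12)
      expect_equal(Q, t(Q))
      want <- oracle_glcm(rg$gray, rg$mask, 4, offs[[nm]][1], offs[[nm]][2])
      expect_equal(Q, want, tolerance = 1e-12)
    }
  }
})

test_that("a one-pixel checkerboard has maximal contrast at distance 1", {
  n <- 16
  cb <- outer(1:n, 1:n, function(i, j) ifelse((i + j) %% 2 == 0, 0L, 255L))
  gl <- buildGLCM(cb, matrix(TRUE, n, n), levels = 8, distance = 1)
  # horizontal neighbours always differ by the full dynamic range
  f0 <- oracle_glcm_scalars(gl$d0$Q)
  expect_equal(f0[["inertia"]], (8 - 1)^2)
})

test_that("GLCM direction statistics match direct summation", {
  for (s in c(9, 10)) {
    rg <- random_gray(s, n = 8)
    gl <- buildGLCM(rg$gray, matrix(TRUE, 8, 8), levels = 4)
    got <- glcmFeatures(gl)
    per <- sapply(gl, function(g) oracle_glcm_scalars(g$Q))
    mn <- rowMeans(per)
    sdv <- sqrt(rowMeans((per - mn)^2))
    expect_equal(unname(got),
                 unname(c(mn, sdv)[c(1, 2, 3, 4, 5, 6, 7, 8)]),
                 tolerance = 1e-9)
  }
})

test_that("the assembled 36-vector is the ordered concatenation of its parts", {
  img <- makeLeafImage(13, 0.18, size = c(48, 48), noise_sd = 3)
  mask <- segmentLeaf(img)
  v <- extractFeatures(img, mask)
  expect_length(v, 36)
  expect_identical(names(v), featureNames())
  expect_true(all(is.finite(v)))
  cfg <- featureConfig()
  parts <- c(colorFeatures(rgbImage(img), mask),
             histogramFeatures(grayImage(img), mask),
             ggcmFeatures(buildGGCM(grayImage(img), mask, cfg$Ng, cfg$Ns, cfg$T)),
             glcmFeatures(buildGLCM(grayImage(img), mask, cfg$glcm_levels,
                                    cfg$glcm_distance)))
  expect_identical(v, parts)
  expect_identical(v, extractFeatures(img, mask))
  # documented range invariants
  expect_gte(v[["hist_smooth"]], 0); expect_lt(v[["hist_smooth"]], 1)
  expect_gt(v[["energy_mean"]], 0); expect_lte(v[["energy_mean"]], 1)
  expect_gte(v[["entropy_mean"]], 0)
})

test_that("gray-image features respond monotonically to the injured fraction", {
  targets <- seq(0.02, 0.5, length.out = 20)
  feats <- t(sapply(seq_along(targets), function(k) {
    img <- makeLeafImage(500 + k, targets[k], size = c(48, 48), noise_sd = 3)
    mask <- leafTruth(img)@leaf_mask
    histogramFeatures(grayImage(img), mask)
  }))
  expect_lt(stats::cor(targets, feats[, "hist_mean"], method = "spearman"), -0.8)
  expect_gt(stats::cor(targets, feats[, "hist_sd"], method = "spearman"), 0.8)
})
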