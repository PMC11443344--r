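test_that("tie-free Spearman equals the classical rank-difference form", {
  expect_equal(spearmanRho(1:5, c(2, 4, 6, 8, 10)), 1)
  # sum(d^2) = 4 -> 1 - 24/120
  expect_equal(spearmanRho(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_equal(spearmanRho(1:6, 6:1), -1)
  expect_error(spearmanRho(1:4, 1:5))
  expect_error(spearmanRho(1:2, 2:1))
  expect_error(spearmanRho(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_warning(r0 <- spearmanRho(c(2, 2, 2), 1:3), "constant")
  expect_equal(r0, 0)
})

test_that("tied data matches the rank-then-correlate oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- sample(1:6, 20, replace = TRUE)
    y <- rep(1:4, each = 5)
    expect_equal(spearmanRho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(spearmanRho(x, y),
                 suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms of x", {
  set.seed(5)
  x <- stats::rnorm(30); y <- rep(1:4, length.out = 30) + 0.3 * x
  r <- spearmanRho(x, y)
  expect_equal(spearmanRho(exp(x), y), r, tolerance = 1e-12)
  expect_equal(spearmanRho(x^3, y), r, tolerance = 1e-12)
})

test_that("strength bins follow the screening convention and partition [0,1]", {
  expect_equal(as.character(classifyStrength(0.893)), "very_strong")
  expect_equal(as.character(classifyStrength(-0.555)), "strong")
  expect_equal(as.character(classifyStrength(0.417)), "moderate")
  expect_equal(as.character(classifyStrength(0.076)), "weak")
  expect_equal(as.character(classifyStrength(0)), "weak")
  expect_equal(as.character(classifyStrength(c(0.3, 0.5, 0.8, 1))),
               c("moderate", "strong", "very_strong", "very_strong"))
  expect_error(classifyStrength(1.01))
  grid <- seq(-1, 1, by = 0.001)
  expect_false(anyNA(classifyStrength(grid)))
})

test_that("the published correlation table screens to exactly nine features", {
  ref <- reference_spearman_table()
  strength <- classifyStrength(ref$rho)
  picked <- ref$feature[strength == "very_strong"]
  expect_length(picked, 9)
  expect_setequal(picked, selectedFeatureNames())
})

test_that("screening a feature table returns the very-strong group in canonical order", {
  set.seed(77)
  n <- 40
  level <- rep(1:4, each = 10)
  tab <- data.frame(
    hist_mean = level + stats::rnorm(n, sd = 0.1),   # near-perfect
    B = stats::rnorm(n),                              # pure noise
    grad_mean = -level + stats::rnorm(n, sd = 0.1)    # strong negative
  )
  sel <- selectFeatures(tab, gradeLabels()[level])
  expect_equal(sel$selected, c("hist_mean", "grad_mean"))
  expect_equal(nrow(sel$report), 3)
  # a feature equal to the grade level itself is always selected
  tab$exact <- level
  expect_true("exact" %in% selectFeatures(tab, gradeLabels()[level])$selected)
})

test_that("selection is empty (with a warning) on permuted-label null data", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    tab <- as.data.frame(matrix(stats::rnorm(60 * 5), 60, 5))
    grades <- sample(rep(gradeLabels(), each = 15))
    sel <- suppressWarnings(selectFeatures(tab, grades))
    if (length(sel$selected) == 0) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of runs
})

test_that("selection is invariant to row order", {
  set.seed(9)
  level <- rep(1:4, each = 8)
  tab <- data.frame(f1 = level + stats::rnorm(32, sd = 0.05),
                    f2 = stats::rnorm(32))
  perm <- sample(32)
  a <- selectFeatures(tab, gradeLabels()[level])
  b <- selectFeatures(tab[perm, ], gradeLabels()[level][perm])
  expect_equal(a$selected, b$selected)
  expect_equal(a$report$rho, b$report$rho, tolerance = 1e-12)
})
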