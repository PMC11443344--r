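test_that("roller update follows the rolling rule and respects the box", {
  # worst position equal to current: light term vanishes
  expect_equal(dboRollUpdate(2, 1, 2, k = 0.1, b_roll = 0.3, alpha = 1,
                             lower = -10, upper = 10),
               2 + 0.1 * 1)
  # 2 + 0.1*1 + 0.3*|2-5| = 3.0
  expect_equal(dboRollUpdate(2, 1, 5, k = 0.1, b_roll = 0.3, alpha = 1,
                             lower = -10, upper = 10), 3.0)
  # componentwise absolute value and clipping
  out <- dboRollUpdate(c(4, -4), c(10, -10), c(0, 0), k = 0.2, b_roll = 0.9,
                       alpha = 1, lower = c(-5, -5), upper = c(5, 5))
  expect_true(all(out >= -5 & out <= 5))
})

test_that("brood update collapses its spawning region as R shrinks", {
  lb <- rep(-5, 3); ub <- rep(5, 3)
  xstar <- c(1, -2, 3)
  # R = 0: region is the point X*, so the egg lands exactly there
  expect_equal(dboBroodUpdate(c(4, 4, 4), xstar, R = 0, lb, ub), xstar)
  # forced b1 = b2 = 0 with a collapsed-to-X* region returns X*
  xout <- c(12, -14, 12)  # X*(1-R) outside the box -> inverted region
  expect_equal(dboBroodUpdate(c(0, 0, 0), xout, R = 0.5, lb, ub,
                              b1 = rep(0, 3), b2 = rep(0, 3)),
               pmin(pmax(xout, lb), ub))
  # result always lies inside the global box
  set.seed(1)
  for (i in 1:20) {
    out <- dboBroodUpdate(stats::runif(3, -5, 5), stats::runif(3, -5, 5),
                          R = stats::runif(1), lb, ub)
    expect_true(all(out >= lb & out <= ub))
  }
})

test_that("forager update obeys its zero and degenerate cases", {
  lb <- rep(-5, 2); ub <- rep(5, 2)
  x <- c(1, -1)
  expect_equal(dboForageUpdate(x, c(2, 2), R = 0.5, lb, ub,
                               C1 = 0, C2 = rep(0, 2)), x)
  # x_t sitting exactly on a collapsed feeding region never moves
  xb <- c(1, -1)  # R = 0 -> Lbb = Ubb = Xb
  expect_equal(dboForageUpdate(xb, xb, R = 0, lb, ub,
                               C1 = 2.3, C2 = c(0.9, 0.4)), xb)
  set.seed(2)
  for (i in 1:20) {
    out <- dboForageUpdate(stats::runif(2, -5, 5), stats::runif(2, -5, 5),
                           R = stats::runif(1), lb, ub)
    expect_true(all(out >= lb & out <= ub))
  }
})

test_that("the optimizer contract holds: monotone record, box, determinism", {
  sphere <- function(x) sum(x^2)
  cfg <- dboConfig(pop_size = 12, max_iter = 30, lower = rep(-3, 2),
                   upper = rep(3, 2), seed = 4)
  res <- dboOptimize(sphere, cfg)
  expect_length(res$history, 30)
  expect_true(all(diff(res$history) <= 0))
  expect_true(all(res$population >= -3 & res$population <= 3))
  expect_equal(res$best_fitness, sphere(res$best_position))

  res2 <- dboOptimize(sphere, cfg)
  expect_identical(res$history, res2$history)
  res3 <- dboOptimize(sphere, dboConfig(pop_size = 12, max_iter = 30,
                                        lower = rep(-3, 2), upper = rep(3, 2),
                                        seed = 5))
  expect_false(identical(res$history, res3$history))
})

test_that("zero iterations returns the best of the initial population", {
  cfg <- dboConfig(pop_size = 10, max_iter = 0, lower = -2, upper = 2, seed = 6)
  res <- dboOptimize(function(x) (x - 0.5)^2, cfg)
  expect_length(res$history, 0)
  expect_equal(res$best_fitness, min(res$fitness))
})

test_that("an all-roller population with vanishing coefficients is stationary", {
  cfg <- dboConfig(pop_size = 8, max_iter = 5, k = 1e-12, b_roll = 1e-12,
                   role_fractions = c(1, 0, 0), lower = rep(-4, 2),
                   upper = rep(4, 2), seed = 7)
  res <- dboOptimize(function(x) sum(x^2), cfg)
  set.seed(7)
  init <- matrix(stats::runif(8 * 2, rep(-4, each = 8), rep(4, each = 8)), 8, 2)
  expect_lt(max(abs(res$population - init)), 1e-6)
})

test_that("a non-finite objective value is reported with the position", {
  cfg <- dboConfig(pop_size = 4, max_iter = 1, lower = -1, upper = 1, seed = 8)
  expect_error(dboOptimize(function(x) NaN, cfg), "non-finite objective")
})
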