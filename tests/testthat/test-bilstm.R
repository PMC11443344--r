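test_that("a freshly built model emits proper class distributions", {
  cfg <- bilstmConfig(hidden_units = 8, seed = 11)
  m <- bilstmBuild(cfg, input_len = 9)
  set.seed(1)
  X <- matrix(stats::rnorm(45), 5, 9)
  p <- bilstmPredict(m, X)
  expect_equal(rowSums(p$probs), rep(1, 5), tolerance = 1e-6)
  # same seed -> identical initial predictions
  m2 <- bilstmBuild(cfg, input_len = 9)
  expect_identical(bilstmPredict(m2, X)$probs, p$probs)
  # minimal capacity still runs
  m1 <- bilstmBuild(bilstmConfig(hidden_units = 1, seed = 2), input_len = 9)
  expect_equal(rowSums(bilstmPredict(m1, X)$probs), rep(1, 5),
               tolerance = 1e-6)
})

test_that("analytic gradients match finite differences on a tiny model", {
  hd <- 3L
  cfg <- bilstmConfig(hidden_units = hd, l2 = 0.01, max_epochs = 1, seed = 3)
  model <- bilstmBuild(cfg, input_len = 4)
  set.seed(4)
  X <- matrix(stats::rnorm(5 * 4), 5, 4)
  y <- c("A", "B", "C", "D", "B")
  idx <- match(y, gradeLabels())
  Y <- matrix(0, 5, 4); Y[cbind(1:5, idx)] <- 1

  lossAt <- function(theta) {
    p <- fluorChill:::paramFromVec(theta, hd)
    fw <- fluorChill:::bilstmForward(list(params = p, config = cfg), X)
    ce <- -mean(log(fw$probs[cbind(1:5, idx)]))
    ce + 0.5 * cfg$l2 * (sum(p$fwd$Wx^2) + sum(p$fwd$Wh^2) +
                         sum(p$bwd$Wx^2) + sum(p$bwd$Wh^2) + sum(p$Wout^2))
  }
  theta <- fluorChill:::paramVec(model$params)
  p <- fluorChill:::paramFromVec(theta, hd)
  fw <- fluorChill:::bilstmForward(list(params = p, config = cfg), X)
  dlogits <- (fw$probs - Y) / 5
  dWout <- crossprod(fw$hcat, dlogits) + cfg$l2 * p$Wout
  dhcat <- dlogits %*% t(p$Wout)
  gf <- fluorChill:::lstmBackwardDir(fw$fwd, p$fwd,
                                     dhcat[, 1:hd, drop = FALSE], hd)
  gb <- fluorChill:::lstmBackwardDir(fw$bwd, p$bwd,
                                     dhcat[, (hd + 1):(2 * hd), drop = FALSE],
                                     hd)
  gf$Wx <- gf$Wx + cfg$l2 * p$fwd$Wx; gf$Wh <- gf$Wh + cfg$l2 * p$fwd$Wh
  gb$Wx <- gb$Wx + cfg$l2 * p$bwd$Wx; gb$Wh <- gb$Wh + cfg$l2 * p$bwd$Wh
  grad <- c(gf$Wx, gf$Wh, gf$b, gb$Wx, gb$Wh, gb$b, dWout, colSums(dlogits))

  eps <- 1e-6
  check <- sample(length(theta), 25)
  for (k in check) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    num <- (lossAt(tp) - lossAt(tm)) / (2 * eps)
    expect_equal(grad[k], num, tolerance = 1e-4)
  }
})

test_that("training fits well-separated classes and logs its loss", {
  tab <- makeFeatureTable(21, 100, 5)
  X <- as.matrix(tab[, -1]); y <- tab$grade
  cfg <- bilstmConfig(hidden_units = 24, learning_rate = 0.02,
                      max_epochs = 120, seed = 5)
  m <- bilstmTrain(bilstmBuild(cfg, 9), X, y)
  expect_length(m$loss_history, 120)
  expect_lte(m$loss_history[120], m$loss_history[1])
  acc <- mean(bilstmPredict(m, X)$labels == y)
  expect_gte(acc, 0.99)
})

test_that("training errors are informative", {
  tab <- makeFeatureTable(22, 10, 2)
  X <- as.matrix(tab[, -1])
  m <- bilstmBuild(bilstmConfig(hidden_units = 4, max_epochs = 2, seed = 6), 9)
  y_missing <- tab$grade
  y_missing[y_missing == "D"] <- "A"
  expect_error(bilstmTrain(m, X, y_missing), "four grades")
  expect_error(bilstmTrain(m, X[, 1:5], tab$grade), "expected 9")
  expect_error(bilstmPredict(m, X[, 1:5]), "expected 9")
})

test_that("null-signal data scores inside the chance band", {
  tr <- makeFeatureTable(23, 50, 0)
  te <- makeFeatureTable(24, 50, 0)  # 200 test rows
  cfg <- bilstmConfig(hidden_units = 12, learning_rate = 0.01,
                      max_epochs = 60, seed = 7)
  m <- bilstmTrain(bilstmBuild(cfg, 9), as.matrix(tr[, -1]), tr$grade)
  acc <- mean(bilstmPredict(m, as.matrix(te[, -1]))$labels == te$grade)
  expect_gte(acc, 0.10)
  expect_lte(acc, 0.45)
})

test_that("32 random samples are memorized at hidden size 64", {
  set.seed(8)
  X <- matrix(stats::rnorm(32 * 9), 32, 9)
  y <- rep(gradeLabels(), each = 8)
  cfg <- bilstmConfig(hidden_units = 64, learning_rate = 0.01,
                      max_epochs = 500, seed = 9)
  m <- bilstmTrain(bilstmBuild(cfg, 9), X, y)
  expect_equal(mean(bilstmPredict(m, X)$labels == y), 1)
})

test_that("prediction is deterministic, order-invariant and argmax-consistent", {
  tab <- makeFeatureTable(25, 20, 3)
  X <- as.matrix(tab[, -1]); y <- tab$grade
  cfg <- bilstmConfig(hidden_units = 10, max_epochs = 40, seed = 10)
  m1 <- bilstmTrain(bilstmBuild(cfg, 9), X, y)
  m2 <- bilstmTrain(bilstmBuild(cfg, 9), X, y)
  p1 <- bilstmPredict(m1, X); p2 <- bilstmPredict(m2, X)
  expect_identical(p1$probs, p2$probs)
  perm <- sample(nrow(X))
  pp <- bilstmPredict(m1, X[perm, ])
  expect_equal(pp$probs, p1$probs[perm, ])
  expect_equal(as.integer(p1$labels), max.col(p1$probs, ties.method = "first"))
})

test_that("DBO tuning stays in the search box and never worsens the record", {
  tab <- makeFeatureTable(26, 20, 3)
  X <- as.matrix(tab[, -1]); y <- tab$grade
  box <- tuningBox()
  base <- bilstmConfig(max_epochs = 15, seed = 12)
  dcfg0 <- dboConfig(pop_size = 4, max_iter = 0, lower = box$lower,
                     upper = box$upper, seed = 13)
  dcfg2 <- dboConfig(pop_size = 4, max_iter = 2, lower = box$lower,
                     upper = box$upper, seed = 13)
  t0 <- tuneBiLSTM(X, y, dbo_config = dcfg0, base_config = base,
                   tune_epochs = 15)
  t2 <- tuneBiLSTM(X, y, dbo_config = dcfg2, base_config = base,
                   tune_epochs = 15)
  # same seed -> same initial population; more iterations cannot be worse
  expect_lte(t2$best_fitness, t0$best_fitness)
  expect_length(t2$history, 2)
  bc <- t2$best_config
  expect_gte(bc$hidden_units, 5); expect_lte(bc$hidden_units, 100)
  expect_gte(bc$learning_rate, 1e-4); expect_lte(bc$learning_rate, 0.1)
  expect_gte(bc$l2, 1e-4); expect_lte(bc$l2, 0.1)
})

test_that("tuning does not hurt accuracy on separable data (median over seeds)", {
  diffs <- sapply(1:5, function(s) {
    tr <- makeFeatureTable(30 + s, 40, 3)
    te <- makeFeatureTable(60 + s, 25, 3)
    Xtr <- as.matrix(tr[, -1]); Xte <- as.matrix(te[, -1])
    base <- bilstmConfig(hidden_units = 20, learning_rate = 0.005,
                         max_epochs = 60, seed = s)
    untuned <- bilstmTrain(bilstmBuild(base, 9), Xtr, tr$grade)
    acc_u <- mean(bilstmPredict(untuned, Xte)$labels == te$grade)
    box <- tuningBox()
    tn <- tuneBiLSTM(Xtr, tr$grade,
                     dbo_config = dboConfig(pop_size = 5, max_iter = 2,
                                            lower = box$lower,
                                            upper = box$upper,
                                            seed = 90 + s),
                     base_config = base, tune_epochs = 25)
    cfg <- tn$best_config; cfg$max_epochs <- 60L
    tuned <- bilstmTrain(bilstmBuild(cfg, 9), Xtr, tr$grade)
    acc_t <- mean(bilstmPredict(tuned, Xte)$labels == te$grade)
    acc_t - acc_u
  })
  expect_gte(stats::median(diffs), -0.05)
})
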