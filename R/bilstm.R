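#' BiLSTM configuration
#'
#' Baseline settings follow the study setup for this model family: 200
#' hidden units, initial learning rate 0.001, L2 coefficient 0.001, up to
#' 500 training epochs with the learning rate multiplied once by 0.1 at
#' mid-training. The tuner searches hidden units in `[5, 100]` and both
#' rates in `[1e-4, 0.1]` (log scale).
#'
#' @param hidden_units hidden state size per direction (at least 1).
#' @param learning_rate initial Adam step size (> 0).
#' @param l2 L2 penalty coefficient on the weight matrices (>= 0).
#' @param max_epochs full-batch training epochs.
#' @param lr_drop_factor factor applied to the learning rate once, at epoch
#'   `ceiling(max_epochs / 2)`.
#' @param seed integer seed controlling initialization (training itself is
#'   full-batch, hence deterministic given the initialization).
#' @return Named list of class `bilstm_config`.
#' @export
bilstmConfig <- function(hidden_units = 200L, learning_rate = 0.001,
                         l2 = 0.001, max_epochs = 500L,
                         lr_drop_factor = 0.1, seed = 1L) {
  stopifnot(hidden_units >= 1, learning_rate > 0, l2 >= 0, max_epochs >= 1,
            lr_drop_factor > 0, lr_drop_factor <= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, l2 = l2,
                 max_epochs = as.integer(max_epochs),
                 lr_drop_factor = lr_drop_factor, seed = as.integer(seed)),
            class = "bilstm_config")
}

# Glorot-uniform initialization of one LSTM direction + shared head sizes.
# Gate column layout in all 4H-wide matrices: [input, forget, cell, output].
initLstmDir <- function(hd) {
  gl <- function(nin, nout, ncol_) {
    r <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * ncol_, -r, r), nin, ncol_)
  }
  b <- numeric(4 * hd)
  b[(hd + 1):(2 * hd)] <- 1  # forget-gate bias at 1: remember by default
  list(Wx = gl(1, hd, 4 * hd), Wh = gl(hd, hd, 4 * hd), b = b)
}

#' Build a BiLSTM grade classifier
#'
#' Each sample is treated as a length-`input_len` sequence of scalars (one
#' feature per time step, in the screened-feature order); a forward and a
#' backward LSTM pass run over the sequence, their final hidden states are
#' concatenated (the dense head's weights subsume any fixed combination
#' coefficients of the two directions) and mapped to 4 softmax logits.
#'
#' @param config a [bilstmConfig()].
#' @param input_len sequence length (number of input features), default 9.
#' @return List of class `bilstm_model` (untrained).
#' @export
bilstmBuild <- function(config = bilstmConfig(), input_len = 9L) {
  stopifnot(inherits(config, "bilstm_config"), input_len >= 1)
  set.seed(config$seed)
  hd <- config$hidden_units
  r <- sqrt(6 / (2 * hd + 4))
  params <- list(
    fwd = initLstmDir(hd),
    bwd = initLstmDir(hd),
    Wout = matrix(stats::runif(2 * hd * 4, -r, r), 2 * hd, 4),
    bout = numeric(4)
  )
  structure(list(params = params, config = config,
                 seq_len = as.integer(input_len), n_class = 4L,
                 center = NULL, scale = NULL, trained = FALSE,
                 loss_history = numeric(0)),
            class = "bilstm_model")
}

# one full LSTM pass over the sequence; X is n x T (standardized),
# returns final hidden state and the per-step cache for BPTT
lstmForwardDir <- function(X, p, hd, reverse = FALSE) {
  n <- nrow(X); Tn <- ncol(X)
  steps <- if (reverse) Tn:1 else 1:Tn
  h <- matrix(0, n, hd); cc <- matrix(0, n, hd)
  cache <- vector("list", Tn)
  ii <- 1:hd; ff <- (hd + 1):(2 * hd); gg <- (2 * hd + 1):(3 * hd)
  oo <- (3 * hd + 1):(4 * hd)
  for (s in seq_along(steps)) {
    xt <- X[, steps[s], drop = FALSE]
    z <- xt %*% p$Wx + h %*% p$Wh + matrix(p$b, n, 4 * hd, byrow = TRUE)
    i_g <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    f_g <- 1 / (1 + exp(-z[, ff, drop = FALSE]))
    g_g <- tanh(z[, gg, drop = FALSE])
    o_g <- 1 / (1 + exp(-z[, oo, drop = FALSE]))
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    cache[[s]] <- list(xt = xt, i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h_last = h, cache = cache, steps = steps)
}

# BPTT for one direction given the gradient of the loss wrt the final h
lstmBackwardDir <- function(fwd, p, dh_last, hd) {
  Tn <- length(fwd$cache)
  n <- nrow(dh_last)
  dWx <- matrix(0, 1, 4 * hd); dWh <- matrix(0, hd, 4 * hd)
  db <- numeric(4 * hd)
  dh <- dh_last; dc <- matrix(0, n, hd)
  for (s in Tn:1) {
    cs <- fwd$cache[[s]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    Z <- cbind(di * cs$i * (1 - cs$i),
               df * cs$f * (1 - cs$f),
               dg * (1 - cs$g^2),
               do_ * cs$o * (1 - cs$o))
    dWx <- dWx + crossprod(cs$xt, Z)
    dWh <- dWh + crossprod(cs$h_prev, Z)
    db <- db + colSums(Z)
    dh <- Z %*% t(p$Wh)
    dc <- dc * cs$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

bilstmForward <- function(model, X) {
  p <- model$params; hd <- model$config$hidden_units
  fwd <- lstmForwardDir(X, p$fwd, hd, reverse = FALSE)
  bwd <- lstmForwardDir(X, p$bwd, hd, reverse = TRUE)
  hcat <- cbind(fwd$h_last, bwd$h_last)
  logits <- hcat %*% p$Wout + matrix(p$bout, nrow(X), 4, byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  list(probs = probs, hcat = hcat, fwd = fwd, bwd = bwd)
}

# flatten / restore helpers for Adam over the nested parameter list
paramVec <- function(p) {
  c(p$fwd$Wx, p$fwd$Wh, p$fwd$b, p$bwd$Wx, p$bwd$Wh, p$bwd$b, p$Wout, p$bout)
}
paramFromVec <- function(v, hd) {
  at <- 0
  take <- function(k) { out <- v[(at + 1):(at + k)]; at <<- at + k; out }
  dir_ <- function() {
    list(Wx = matrix(take(4 * hd), 1, 4 * hd),
         Wh = matrix(take(hd * 4 * hd), hd, 4 * hd),
         b = take(4 * hd))
  }
  fwd <- dir_(); bwd <- dir_()
  list(fwd = fwd, bwd = bwd,
       Wout = matrix(take(2 * hd * 4), 2 * hd, 4), bout = take(4))
}

encodeLabels <- function(y, n) {
  g <- as.character(y)
  if (!all(g %in% gradeLabels())) stop("unknown grade label")
  idx <- match(g, gradeLabels())
  Y <- matrix(0, n, 4)
  Y[cbind(seq_len(n), idx)] <- 1
  list(Y = Y, idx = idx)
}

#' Train the BiLSTM
#'
#' Full-batch Adam on cross-entropy plus `l2 / 2 * sum(W^2)` over the
#' weight matrices (biases unpenalized), with global gradient-norm clipping
#' at 1 and the learning rate multiplied by `lr_drop_factor` once at epoch
#' `ceiling(max_epochs / 2)`. Features are z-scored on the training set and
#' the scaling is stored in the model for prediction. Deterministic given
#' the configuration seed (full-batch training has no sampling noise).
#'
#' @param model a [bilstmBuild()] model.
#' @param X numeric `n x seq_len` feature matrix (at least 8 rows).
#' @param y grade labels, all four grades present.
#' @param standardize z-score the columns of `X` (recommended; feature
#'   scales span several orders of magnitude).
#' @return The trained model; `$loss_history` has one entry per epoch.
#' @export
bilstmTrain <- function(model, X, y, standardize = TRUE) {
  stopifnot(inherits(model, "bilstm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$seq_len)
    stop(sprintf("expected %d features, got %d", model$seq_len, ncol(X)))
  n <- nrow(X)
  if (n < 8) stop("need at least 8 training samples")
  enc <- encodeLabels(y, n)
  if (length(unique(enc$idx)) < 4) stop("all four grades must be present in y")

  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scl, `/`)

  cfg <- model$config
  hd <- cfg$hidden_units
  theta <- paramVec(model$params)
  m_ <- numeric(length(theta)); v_ <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  drop_at <- ceiling(cfg$max_epochs / 2)
  loss_hist <- numeric(cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    if (epoch == drop_at) lr <- lr * cfg$lr_drop_factor
    p <- paramFromVec(theta, hd)
    fw <- bilstmForward(list(params = p, config = cfg), Xs)
    probs <- fw$probs
    ce <- -mean(log(pmax(probs[cbind(seq_len(n), enc$idx)], 1e-12)))
    pen <- 0.5 * cfg$l2 * (sum(p$fwd$Wx^2) + sum(p$fwd$Wh^2) +
                           sum(p$bwd$Wx^2) + sum(p$bwd$Wh^2) + sum(p$Wout^2))
    loss_hist[epoch] <- ce + pen

    dlogits <- (probs - enc$Y) / n
    dWout <- crossprod(fw$hcat, dlogits) + cfg$l2 * p$Wout
    dbout <- colSums(dlogits)
    dhcat <- dlogits %*% t(p$Wout)
    gf <- lstmBackwardDir(fw$fwd, p$fwd, dhcat[, 1:hd, drop = FALSE], hd)
    gb <- lstmBackwardDir(fw$bwd, p$bwd,
                          dhcat[, (hd + 1):(2 * hd), drop = FALSE], hd)
    gf$Wx <- gf$Wx + cfg$l2 * p$fwd$Wx; gf$Wh <- gf$Wh + cfg$l2 * p$fwd$Wh
    gb$Wx <- gb$Wx + cfg$l2 * p$bwd$Wx; gb$Wh <- gb$Wh + cfg$l2 * p$bwd$Wh
    grad <- c(gf$Wx, gf$Wh, gf$b, gb$Wx, gb$Wh, gb$b, dWout, dbout)

    gn <- sqrt(sum(grad^2))
    if (gn > 1) grad <- grad / gn  # global-norm clip at 1

    m_ <- beta1 * m_ + (1 - beta1) * grad
    v_ <- beta2 * v_ + (1 - beta2) * grad^2
    mh <- m_ / (1 - beta1^epoch)
    vh <- v_ / (1 - beta2^epoch)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
  }

  model$params <- paramFromVec(theta, hd)
  model$center <- center
  model$scale <- scl
  model$trained <- TRUE
  model$loss_history <- loss_hist
  model
}

#' Predict grades with a BiLSTM
#'
#' @param model a built (or trained) `bilstm_model`.
#' @param X numeric `n x seq_len` feature matrix.
#' @return List: `labels` (factor A-D; argmax probability, ties broken
#'   toward the lower class index) and `probs` (`n x 4`, rows sum to 1).
#' @export
bilstmPredict <- function(model, X) {
  stopifnot(inherits(model, "bilstm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$seq_len)
    stop(sprintf("expected %d features, got %d", model$seq_len, ncol(X)))
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  probs <- bilstmForward(model, X)$probs
  colnames(probs) <- gradeLabels()
  idx <- max.col(probs, ties.method = "first")
  list(labels = factor(gradeLabels()[idx], levels = gradeLabels()),
       probs = probs)
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf(
    "BiLSTM grade classifier: %d hidden units/direction, %d-step input, %s\n",
    x$config$hidden_units, x$seq_len,
    if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                           length(x$loss_history),
                           x$loss_history[length(x$loss_history)])
    else "untrained"))
  invisible(x)
}
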