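#' Hyperparameter search box for BiLSTM tuning
#'
#' Learning rate in `[1e-4, 0.1]` and L2 coefficient in `[1e-4, 0.1]`
#' (both searched on the log10 scale since the ranges span three orders of
#' magnitude) and hidden units in `[5, 100]` (rounded to the nearest
#' integer at evaluation).
#'
#' @return List with `lower` and `upper` numeric(3):
#'   (log10 learning rate, hidden units, log10 l2).
#' @export
tuningBox <- function() {
  list(lower = c(log10(1e-4), 5, log10(1e-4)),
       upper = c(log10(0.1), 100, log10(0.1)))
}

# decode a DBO position into a concrete training configuration
positionToConfig <- function(pos, base_config, max_epochs = NULL) {
  bilstmConfig(hidden_units = as.integer(round(pos[2])),
               learning_rate = 10^pos[1], l2 = 10^pos[3],
               max_epochs = max_epochs %||% base_config$max_epochs,
               lr_drop_factor = base_config$lr_drop_factor,
               seed = base_config$seed)
}

# stratified index sample: `frac` of each class (at least 1 per class)
stratifiedHoldout <- function(labels, frac, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(labels), as.character(labels)),
                       function(ix) {
                         k <- max(1L, round(frac * length(ix)))
                         ix[sample.int(length(ix), k)]
                       }))
  sort(unname(idx))
}

#' Tune BiLSTM hyperparameters with the dung beetle optimizer
#'
#' Searches the 3-D box of [tuningBox()] with [dboOptimize()]; the fitness
#' of a position is the misclassification rate of a model trained with the
#' decoded configuration and scored on the evaluation split. By default a
#' stratified 25 percent validation split is carved out of the training
#' data (tuning on the test set leaks it into model selection);
#' `paper_mode = TRUE` instead scores fitness directly on the supplied
#' evaluation set and trains on all training rows, mirroring the original
#' protocol this workflow descends from.
#'
#' @param train_x,train_y training features (`n x D`) and grade labels.
#' @param eval_x,eval_y held-out features/labels; required when
#'   `paper_mode = TRUE`, ignored otherwise.
#' @param dbo_config a [dboConfig()] whose bounds default to [tuningBox()].
#' @param base_config a [bilstmConfig()] supplying epochs, drop factor and
#'   seed for every candidate.
#' @param tune_epochs training epochs used while scoring candidates
#'   (candidate models need not be trained to full length to rank them);
#'   defaults to `base_config$max_epochs`.
#' @param paper_mode logical; see above.
#' @return List: `best_config` (a [bilstmConfig()]), `best_fitness`
#'   (misclassification rate), `history` (best-so-far per iteration) and
#'   `dbo` (the raw [dboOptimize()] result).
#' @export
tuneBiLSTM <- function(train_x, train_y, eval_x = NULL, eval_y = NULL,
                       dbo_config = NULL, base_config = bilstmConfig(),
                       tune_epochs = NULL, paper_mode = FALSE) {
  train_x <- as.matrix(train_x)
  box <- tuningBox()
  if (is.null(dbo_config))
    dbo_config <- dboConfig(lower = box$lower, upper = box$upper)

  if (paper_mode) {
    if (is.null(eval_x) || is.null(eval_y))
      stop("paper_mode requires an evaluation split")
    tr_x <- train_x; tr_y <- train_y
    ev_x <- as.matrix(eval_x); ev_y <- eval_y
  } else {
    hold <- stratifiedHoldout(train_y, 0.25,
                              childSeed(dbo_config$seed, 17L))
    tr_x <- train_x[-hold, , drop = FALSE]; tr_y <- train_y[-hold]
    ev_x <- train_x[hold, , drop = FALSE]; ev_y <- train_y[hold]
  }

  objective <- function(pos) {
    cfg <- positionToConfig(pos, base_config, tune_epochs)
    mdl <- bilstmTrain(bilstmBuild(cfg, input_len = ncol(tr_x)), tr_x, tr_y)
    pred <- bilstmPredict(mdl, ev_x)$labels
    mean(as.character(pred) != as.character(ev_y))
  }

  res <- dboOptimize(objective, dbo_config)
  list(best_config = positionToConfig(res$best_position, base_config),
       best_fitness = res$best_fitness,
       history = res$history,
       dbo = res)
}
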