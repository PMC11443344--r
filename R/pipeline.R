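#' Pipeline configuration
#'
#' Settings for the end-to-end workflow: generate (or load) images, grade
#' them by segmentation, extract the 36 features, screen by Spearman
#' correlation on the training split, optionally tune the classifier with
#' the dung beetle optimizer, train, predict and evaluate. One seed drives
#' every stochastic stage.
#'
#' @param seed run seed.
#' @param train_counts,test_counts per-grade image counts (A-D); defaults
#'   are the 42/46/46/42 + 10/12/12/10 study split (176 train, 44 test).
#' @param size,noise_sd synthetic image geometry and noise level.
#' @param feature_config [featureConfig()] settings.
#' @param bands [segmentationBands()] thresholds.
#' @param tune run DBO hyperparameter tuning before the final fit.
#' @param dbo_pop,dbo_iter DBO population and iteration budget (study
#'   settings: 20 and 8).
#' @param tune_epochs candidate-training epochs during tuning.
#' @param bilstm baseline [bilstmConfig()]; also the final-fit epochs.
#' @param paper_mode tune fitness on the test split instead of a carved
#'   validation split (leaky; mirrors the original protocol).
#' @param min_features if Spearman screening selects fewer features than
#'   this, fall back to the canonical nine screened gray-image features.
#' @return Named list of class `pipeline_config`.
#' @export
pipelineConfig <- function(seed = 1L,
                           train_counts = c(42L, 46L, 46L, 42L),
                           test_counts = c(10L, 12L, 12L, 10L),
                           size = c(96L, 96L), noise_sd = 4,
                           feature_config = featureConfig(),
                           bands = segmentationBands(),
                           tune = TRUE, dbo_pop = 20L, dbo_iter = 8L,
                           tune_epochs = 40L,
                           bilstm = bilstmConfig(max_epochs = 300L),
                           paper_mode = FALSE, min_features = 2L) {
  structure(list(seed = as.integer(seed), train_counts = train_counts,
                 test_counts = test_counts, size = size,
                 noise_sd = noise_sd, feature_config = feature_config,
                 bands = bands, tune = tune, dbo_pop = as.integer(dbo_pop),
                 dbo_iter = as.integer(dbo_iter),
                 tune_epochs = as.integer(tune_epochs), bilstm = bilstm,
                 paper_mode = paper_mode,
                 min_features = as.integer(min_features)),
            class = "pipeline_config")
}

#' Run the end-to-end grading-and-classification pipeline
#'
#' Stages, in order: synthetic dataset generation (or a supplied dataset),
#' segmentation-based grading, 36-feature extraction, Spearman screening on
#' the training split, optional DBO tuning, BiLSTM training, prediction on
#' the test split and confusion-matrix evaluation. Any stage error aborts
#' with the stage name and cause. When `out_dir` is given, each stage's
#' artifact is written there (feature CSV, screening report, metrics JSON,
#' confusion and F1-curve CSVs) together with the run seed.
#'
#' @param config a [pipelineConfig()].
#' @param dataset optional pre-built dataset (as from [makeLeafDataset()]);
#'   when `NULL` one is generated from the config.
#' @param out_dir optional output directory for artifacts.
#' @return List: `measurements` (per-image grading), `features`,
#'   `selection`, `tuning` (or NULL), `model`, `predictions`, `report`
#'   (a [metricReport()]), `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), dataset = NULL,
                        out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  dataset <- stage("generate", {
    dataset %||% makeLeafDataset(config$seed, config$train_counts,
                                 config$test_counts, config$size,
                                 config$noise_sd)
  })

  measurements <- stage("grade", {
    gradeImages(c(dataset$train, dataset$test), config$bands)
  })

  features <- stage("features", {
    tr <- buildFeatureTable(dataset$train, config$feature_config,
                            config$bands)
    te <- buildFeatureTable(dataset$test, config$feature_config,
                            config$bands)
    tr$split <- "train"; te$split <- "test"
    rbind(tr, te)
  })

  # labels come from the segmentation-based grading, as in the source
  # workflow (ground truth is only used to verify, not to train)
  lab <- measurements$grade[match(features$id, measurements$id)]
  features$grade_measured <- lab
  train_idx <- features$split == "train"

  selection <- stage("select", {
    selectFeatures(features[train_idx, featureNames()], lab[train_idx])
  })
  selected <- selection$selected
  if (length(selected) < config$min_features) {
    warning("screening selected too few features; using the canonical nine")
    selected <- selectedFeatureNames()
  }

  tr_x <- as.matrix(features[train_idx, selected, drop = FALSE])
  tr_y <- lab[train_idx]
  te_x <- as.matrix(features[!train_idx, selected, drop = FALSE])
  te_y <- lab[!train_idx]

  tuning <- NULL
  fit_config <- config$bilstm
  fit_config$seed <- childSeed(config$seed, 23L)
  if (config$tune) {
    tuning <- stage("tune", {
      box <- tuningBox()
      tuneBiLSTM(tr_x, tr_y,
                 eval_x = te_x, eval_y = te_y,
                 dbo_config = dboConfig(pop_size = config$dbo_pop,
                                        max_iter = config$dbo_iter,
                                        lower = box$lower,
                                        upper = box$upper,
                                        seed = childSeed(config$seed, 29L)),
                 base_config = fit_config,
                 tune_epochs = config$tune_epochs,
                 paper_mode = config$paper_mode)
    })
    fit_config$hidden_units <- tuning$best_config$hidden_units
    fit_config$learning_rate <- tuning$best_config$learning_rate
    fit_config$l2 <- tuning$best_config$l2
  }

  model <- stage("train", {
    bilstmTrain(bilstmBuild(fit_config, input_len = ncol(tr_x)), tr_x, tr_y)
  })

  predictions <- stage("predict", {
    pred <- bilstmPredict(model, te_x)
    data.frame(id = features$id[!train_idx],
               actual = as.character(te_y),
               predicted = as.character(pred$labels))
  })

  report <- stage("evaluate", {
    cm <- confusionCounts(predictions$actual, predictions$predicted)
    metricReport(cm, metadata = list(
      seed = config$seed, tuned = config$tune,
      selected_features = selected,
      hidden_units = fit_config$hidden_units,
      learning_rate = fit_config$learning_rate, l2 = fit_config$l2))
  })

  result <- list(measurements = measurements, features = features,
                 selection = selection, tuning = tuning, model = model,
                 predictions = predictions, report = report,
                 config = config)
  if (!is.null(out_dir)) writePipelineArtifacts(result, out_dir)
  result
}

writePipelineArtifacts <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writeFeatureCSV(result$features, file.path(out_dir, "features.csv"))
  utils::write.csv(result$measurements, file.path(out_dir, "grading.csv"),
                   row.names = FALSE)
  writeSelectionReport(result$selection,
                       file.path(out_dir, "spearman_report.csv"),
                       file.path(out_dir, "selected_features.json"))
  utils::write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  writeMetricReport(result$report, file.path(out_dir, "metrics.json"),
                    confusion_csv = file.path(out_dir, "confusion.csv"),
                    f1_csv = file.path(out_dir, "f1_curve.csv"))
  invisible(out_dir)
}
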