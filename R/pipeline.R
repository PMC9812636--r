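#' Pipeline configuration
#'
#' Bundles the settings of every stage: band-pass filter, channel
#' selection, CSSD, and classifier. Defaults follow the field's usual
#' operating point for two-class motor imagery: 8-31 Hz band-pass, 25
#' selected channels scored on mu-band (8-13 Hz) power, J = 10 filters
#' per class (20 features), kernel ELM with C = 10 and an RBF kernel.
#'
#' @param band_low_hz,band_high_hz,filter_order band-pass settings, see
#'   [filter_spec()].
#' @param channels_m channels kept after ranking (default 25; clamped to
#'   the number of available channels).
#' @param select_band_hz band scored by the relative-distance criterion.
#' @param psd_method,ar_order PSD estimator for the ranking, see
#'   [estimate_psd()].
#' @param J CSSD filters per class bank.
#' @param classifier `"elm_kernel"` (default) or `"elm"`.
#' @param C,kernel,gamma kernel-ELM settings, see [train_elm_kernel()].
#' @param n_hidden basic-ELM hidden nodes, see [train_elm()].
#' @param seed integer seed used by every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_low_hz = 8, band_high_hz = 31,
                            filter_order = 4L,
                            channels_m = 25L, select_band_hz = c(8, 13),
                            psd_method = c("burg_ar", "welch"),
                            ar_order = 16L, J = 10L,
                            classifier = c("elm_kernel", "elm"),
                            C = 10, kernel = c("rbf", "linear"),
                            gamma = "median", n_hidden = 100L, seed = 1L) {
  cfg <- structure(list(
    filter = filter_spec(band_low_hz, band_high_hz, filter_order),
    channels_m = as.integer(channels_m),
    select_band_hz = as.numeric(select_band_hz),
    psd_method = match.arg(psd_method),
    ar_order = as.integer(ar_order),
    J = as.integer(J),
    classifier = match.arg(classifier),
    C = as.numeric(C), kernel = match.arg(kernel), gamma = gamma,
    n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
    class = "pipeline_config")
  if (cfg$channels_m < 1L) abort("channels_m must be >= 1.",
                                 class = "cssdelm_config_error")
  if (cfg$J < 1L) abort("J must be >= 1.", class = "cssdelm_config_error")
  if (cfg$C <= 0) abort("C must be > 0.", class = "cssdelm_config_error")
  cfg
}

config_fingerprint <- function(config) rlang::hash(unclass(config))

#' Fit the full classification pipeline on training data
#'
#' Stages run strictly in order, each using training trials only:
#' band-pass filter, channel ranking and selection, CSSD filter-bank fit,
#' feature extraction, classifier training. The fitted object freezes
#' every stage, so prediction never re-estimates anything from test data.
#'
#' @param train an [epoched_recording()] with both classes present.
#' @param config a [pipeline_config()].
#' @param verbose emit per-stage messages (default `FALSE`).
#' @return An object of class `trained_pipeline`: list with `filter`,
#'   `ranking` (train-derived `channel_ranking`), `selected_names`,
#'   `bank` ([fit_cssd()] result), `model` (classifier), `config`,
#'   `fingerprint`, `n_train`.
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 15, seed = 5))
#' cfg <- pipeline_config(J = 3, channels_m = 10, ar_order = 8)
#' fit <- fit_pipeline(rec, cfg)
#' evaluate(fit, rec)$accuracy
#' @export
fit_pipeline <- function(train, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(train, "epoched_recording"),
            inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  fp <- config_fingerprint(config)
  say("pipeline fit: config %s, seed %d, %d training trials",
      fp, config$seed, n_trials(train))

  filt <- stage("bandpass", bandpass(train, config$filter))
  m <- min(config$channels_m, n_channels(filt))
  ranking <- stage("channel_select",
                   rank_channels(filt, band = config$select_band_hz, m = m,
                                 method = config$psd_method,
                                 ar_order = config$ar_order))
  sel <- selected_channels(ranking)
  say("selected %d channels: %s", length(sel),
      paste(ranking$channel_name[sel], collapse = ", "))
  restricted <- stage("channel_select", restrict_channels(filt, sel))

  sp <- stage("cssd", split_by_class(restricted))
  bank <- stage("cssd", fit_cssd(class_covariance(sp$class_a, 1L),
                                 class_covariance(sp$class_b, 2L),
                                 J = config$J,
                                 channel_names = restricted$channel_names))
  feats <- stage("cssd", featurize_recording(restricted, bank))

  model <- stage("classifier", switch(config$classifier,
    elm_kernel = train_elm_kernel(feats, C = config$C,
                                  kernel = config$kernel,
                                  gamma = config$gamma),
    elm = train_elm(feats, n_hidden = config$n_hidden,
                    seed = config$seed)))

  structure(list(filter = config$filter, ranking = ranking,
                 selected_names = restricted$channel_names,
                 bank = bank, model = model, config = config,
                 fingerprint = fp, n_train = n_trials(train)),
            class = "trained_pipeline")
}

# tag stage errors with the stage name, as pipeline errors should read
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(e$cssdelm_stage)) stop(e)   # already tagged upstream
    cls <- grep("^cssdelm_", class(e), value = TRUE)
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
          class = c(cls, "cssdelm_stage_error"), cssdelm_stage = name)
  })
}

#' @export
print.trained_pipeline <- function(x, ...) {
  cat(sprintf(
    "<trained_pipeline> %s over %d channels, J = %d, trained on %d trials\n",
    x$config$classifier, length(x$selected_names), x$bank$J, x$n_train))
  invisible(x)
}

#' Predict imagery classes with a fitted pipeline
#'
#' Applies the frozen filter, channel subset, spatial filter bank and
#' classifier to new trials. Test labels, if present, are ignored.
#'
#' @param model a [fit_pipeline()] result.
#' @param test an [epoched_recording()]; channel names must include every
#'   channel the pipeline selected at training time.
#' @return A tibble with one row per test trial: `trial`, `label`
#'   (predicted), `score_1`, `score_2`.
#' @export
predict_pipeline <- function(model, test) {
  stopifnot(inherits(model, "trained_pipeline"),
            inherits(test, "epoched_recording"))
  if (n_trials(test) == 0L) {
    return(tibble(trial = integer(0), label = integer(0),
                  score_1 = numeric(0), score_2 = numeric(0)))
  }
  idx <- match(model$selected_names, test$channel_names)
  if (anyNA(idx)) {
    abort(paste0("Test recording lacks channels the pipeline needs: ",
                 paste(model$selected_names[is.na(idx)], collapse = ", ")),
          class = "cssdelm_validation_error")
  }
  filt <- bandpass(test, model$filter)
  restricted <- restrict_channels(filt, idx)
  feats <- featurize_recording(restricted, model$bank)
  preds <- stats::predict(model$model, feats)
  dplyr::bind_cols(tibble(trial = seq_len(n_trials(test))),
                   preds)
}

#' @rdname predict_pipeline
#' @param object,newdata,... S3 `predict()` interface: `newdata` is the
#'   test recording.
#' @export
predict.trained_pipeline <- function(object, newdata, ...) {
  predict_pipeline(object, newdata)
}

#' Evaluate a fitted pipeline on labelled test data
#'
#' @param model a [fit_pipeline()] result.
#' @param test a labelled [epoched_recording()].
#' @return An object of class `evaluation_report`: list with `accuracy`,
#'   `per_class_accuracy`, `confusion` (tibble: truth, predicted, n),
#'   `n_train`, `n_test`, `seed`, `fingerprint`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "trained_pipeline"))
  if (n_trials(test) == 0L) {
    abort("Cannot evaluate on an empty test set.",
          class = "cssdelm_validation_error")
  }
  preds <- predict_pipeline(model, test)
  truth <- test$labels
  conf <- tidyr::complete(
    dplyr::count(tibble(truth = truth, predicted = preds$label),
                 .data$truth, .data$predicted),
    truth = 1:2, predicted = 1:2, fill = list(n = 0L))
  per_class <- vapply(1:2, function(cl) {
    if (!any(truth == cl)) return(NA_real_)
    mean(preds$label[truth == cl] == cl)
  }, numeric(1))
  structure(list(
    accuracy = accuracy(preds$label, truth),
    per_class_accuracy = c(class_1 = per_class[1L], class_2 = per_class[2L]),
    confusion = conf,
    n_train = model$n_train, n_test = n_trials(test),
    seed = model$config$seed, fingerprint = model$fingerprint),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.3f on %d test trials (train n = %d)\n",
              x$accuracy, x$n_test, x$n_train))
  print(x$confusion)
  invisible(x)
}

#' Stratified train/test split of a labelled recording
#'
#' Draws a class-balanced random split: either a fixed number of training
#' trials per class or a training fraction (rounded per class, so balance
#' is preserved within one trial).
#'
#' @param recording a labelled [epoched_recording()].
#' @param fraction training fraction in `(0, 1)`; or
#' @param n_per_class exact training trials per class.
#' @param seed integer seed.
#' @return List with `train` and `test`, both [epoched_recording()]s, and
#'   the index vectors `train_idx`, `test_idx`.
#' @export
split_train_test <- function(recording, fraction = NULL, n_per_class = NULL,
                             seed = 1L) {
  stopifnot(inherits(recording, "epoched_recording"))
  if (is.null(fraction) == is.null(n_per_class)) {
    abort("Give exactly one of `fraction` or `n_per_class`.",
          class = "cssdelm_config_error")
  }
  labels <- recording$labels
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(1:2, function(cl) {
      idx <- which(labels == cl)
      k <- if (is.null(fraction)) n_per_class else round(fraction * length(idx))
      if (k < 2L) {
        abort(sprintf("Split leaves %d training trial(s) for class %d; need >= 2.",
                      k, cl),
              class = "cssdelm_config_error")
      }
      if (k >= length(idx)) {
        abort(sprintf("Split leaves no test trials for class %d.", cl),
              class = "cssdelm_config_error")
      }
      sort(sample(idx, k))
    }))
  })
  test_idx <- setdiff(seq_along(labels), train_idx)
  list(train = subset_trials(recording, train_idx),
       test = subset_trials(recording, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

subset_trials <- function(recording, idx) {
  epoched_recording(recording$trials[idx], recording$labels[idx],
                    recording$sampling_rate_hz, recording$channel_names)
}
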