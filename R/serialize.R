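# Text serialization of fitted artifacts (filter banks, classifier models,
# whole pipelines) as a single JSON bundle. Numeric payloads are stored as
# "%.17g" strings so a write/read round trip is bit-exact.

ser_num <- function(x) {
  if (is.matrix(x)) {
    list(dim = dim(x), data = num_full(as.vector(x)))
  } else {
    num_full(as.numeric(x))
  }
}

deser_num <- function(x) {
  if (is.list(x)) {
    matrix(as.numeric(x$data), nrow = x$dim[1L], ncol = x$dim[2L])
  } else {
    as.numeric(x)
  }
}

ser_bank <- function(bank) {
  list(whitening = ser_num(bank$whitening),
       eigvals_a = ser_num(bank$eigvals_a),
       eigvals_b = ser_num(bank$eigvals_b),
       filters_a = ser_num(bank$filters_a),
       filters_b = ser_num(bank$filters_b),
       J = bank$J, rank = bank$rank, channel_names = bank$channel_names)
}

deser_bank <- function(x) {
  structure(list(whitening = deser_num(x$whitening),
                 eigvals_a = deser_num(x$eigvals_a),
                 eigvals_b = deser_num(x$eigvals_b),
                 filters_a = deser_num(x$filters_a),
                 filters_b = deser_num(x$filters_b),
                 J = as.integer(x$J), rank = as.integer(x$rank),
                 channel_names = as.character(x$channel_names)),
            class = "spatial_filter_bank")
}

ser_model <- function(model) {
  if (inherits(model, "elm_kernel_model")) {
    list(type = "elm_kernel",
         train_features = ser_num(model$train_features),
         alpha = ser_num(model$alpha), C = ser_num(model$C),
         kernel = model$kernel, gamma = ser_num(model$gamma))
  } else {
    list(type = "elm",
         input_weights = ser_num(model$input_weights),
         biases = ser_num(model$biases),
         output_weights = ser_num(model$output_weights),
         activation = model$activation, seed = model$seed,
         n_features = model$n_features)
  }
}

deser_model <- function(x) {
  if (identical(x$type, "elm_kernel")) {
    structure(list(train_features = deser_num(x$train_features),
                   alpha = deser_num(x$alpha), C = deser_num(x$C),
                   kernel = x$kernel, gamma = deser_num(x$gamma)),
              class = "elm_kernel_model")
  } else {
    structure(list(input_weights = deser_num(x$input_weights),
                   biases = deser_num(x$biases),
                   output_weights = deser_num(x$output_weights),
                   activation = x$activation, seed = as.integer(x$seed),
                   n_features = as.integer(x$n_features)),
              class = "elm_model")
  }
}

ser_config <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out
}

deser_config <- function(x) {
  pipeline_config(
    band_low_hz = x$filter$low_hz, band_high_hz = x$filter$high_hz,
    filter_order = x$filter$order,
    channels_m = x$channels_m, select_band_hz = as.numeric(x$select_band_hz),
    psd_method = x$psd_method, ar_order = x$ar_order, J = x$J,
    classifier = x$classifier, C = x$C, kernel = x$kernel,
    gamma = if (is.character(x$gamma)) x$gamma else as.numeric(x$gamma),
    n_hidden = x$n_hidden, seed = x$seed)
}

#' Save and reload fitted pipelines as JSON text
#'
#' Everything a fitted pipeline froze at training time — filter settings,
#' channel ranking and selection, the CSSD filter bank, and the classifier
#' state — is written to one self-describing JSON file. Numeric values are
#' stored at full double precision, so the reloaded pipeline is bit-exact
#' and its predictions are identical.
#'
#' @param model a [fit_pipeline()] result.
#' @param path file path for the JSON bundle.
#' @return `write_pipeline()` returns `path` invisibly; `read_pipeline()`
#'   returns the restored `trained_pipeline`.
#' @export
write_pipeline <- function(model, path) {
  stopifnot(inherits(model, "trained_pipeline"))
  payload <- list(
    type = "trained_pipeline",
    filter = unclass(model$filter),
    ranking = list(channel = model$ranking$channel,
                   channel_name = model$ranking$channel_name,
                   h = ser_num(model$ranking$h),
                   rank = model$ranking$rank,
                   selected = model$ranking$selected),
    selected_names = model$selected_names,
    bank = ser_bank(model$bank),
    model = ser_model(model$model),
    config = ser_config(model$config),
    fingerprint = model$fingerprint,
    n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cssdelm_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(x$type, "trained_pipeline")) {
    abort("Not a serialized trained_pipeline bundle.",
          class = "cssdelm_parse_error")
  }
  ranking <- new_channel_ranking(tibble(
    channel = as.integer(x$ranking$channel),
    channel_name = as.character(x$ranking$channel_name),
    h = deser_num(x$ranking$h),
    rank = as.integer(x$ranking$rank),
    selected = as.logical(x$ranking$selected)))
  cfg <- deser_config(x$config)
  structure(list(filter = cfg$filter, ranking = ranking,
                 selected_names = as.character(x$selected_names),
                 bank = deser_bank(x$bank), model = deser_model(x$model),
                 config = cfg, fingerprint = x$fingerprint,
                 n_train = as.integer(x$n_train)),
            class = "trained_pipeline")
}

#' Save and reload a CSSD filter bank as JSON text
#'
#' Lets train-time spatial filters be reloaded for later prediction.
#'
#' @param bank a [fit_cssd()] result.
#' @param path file path.
#' @return `write_filter_bank()` returns `path` invisibly;
#'   `read_filter_bank()` the restored bank.
#' @export
write_filter_bank <- function(bank, path) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  jsonlite::write_json(c(list(type = "spatial_filter_bank"), ser_bank(bank)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  if (!identical(x$type, "spatial_filter_bank")) {
    abort("Not a serialized spatial_filter_bank bundle.",
          class = "cssdelm_parse_error")
  }
  deser_bank(x)
}
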