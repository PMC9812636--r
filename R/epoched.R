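#' Epoched two-class EEG recording
#'
#' The package's universal data currency: a set of equally sized trials
#' (epochs), each an `n_channels x samples_per_trial` real matrix in
#' microvolt-scale arbitrary units, with one class label per trial.
#' Label 1 is the first imagery class (e.g. right hand), label 2 the second
#' (e.g. right foot).
#'
#' @param trials list of numeric matrices, all of identical dimension
#'   `n_channels x samples_per_trial`. Rows are channels (channel-major
#'   storage, the natural orientation for spatial filtering).
#' @param labels integer vector, one per trial, values in `{1, 2}`.
#' @param sampling_rate_hz single positive number, samples per second.
#' @param channel_names optional character vector of channel identifiers,
#'   length `n_channels`; defaults to `"ch01"`, `"ch02"`, ...
#'
#' @return An object of class `epoched_recording`: a list with elements
#'   `trials`, `labels`, `sampling_rate_hz`, `channel_names`.
#' @examples
#' trials <- replicate(4, matrix(rnorm(3 * 100), 3, 100), simplify = FALSE)
#' rec <- epoched_recording(trials, c(1, 2, 1, 2), 250)
#' rec
#' @export
epoched_recording <- function(trials, labels, sampling_rate_hz,
                              channel_names = NULL) {
  if (!is.list(trials)) {
    abort("`trials` must be a list of channel x sample matrices.",
          class = "cssdelm_validation_error")
  }
  if (length(trials) == 0) {
    # trial-less shell (e.g. an empty test set); channel identity must be given
    if (is.null(channel_names)) {
      abort("An empty recording needs explicit `channel_names`.",
            class = "cssdelm_validation_error")
    }
    if (length(labels) != 0) {
      abort("Got labels for an empty trial list.",
            class = "cssdelm_validation_error")
    }
    return(structure(
      list(trials = list(), labels = integer(0),
           sampling_rate_hz = as.numeric(sampling_rate_hz),
           channel_names = as.character(channel_names)),
      class = "epoched_recording"))
  }
  trials <- lapply(trials, function(tr) {
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    storage.mode(tr) <- "double"
    tr
  })
  dims <- dim(trials[[1L]])
  for (i in seq_along(trials)) {
    if (!is.matrix(trials[[i]]) || !identical(dim(trials[[i]]), dims)) {
      abort(sprintf(
        "Trial %d has dimensions %s; expected %d x %d like trial 1.",
        i, paste(dim(trials[[i]]), collapse = " x "), dims[1], dims[2]),
        class = "cssdelm_validation_error")
    }
    if (anyNA(trials[[i]]) || any(!is.finite(trials[[i]]))) {
      abort(sprintf("Trial %d contains non-finite values.", i),
            class = "cssdelm_validation_error")
    }
  }
  if (dims[1] < 2L) {
    abort("Recordings need at least 2 channels.",
          class = "cssdelm_validation_error")
  }
  if (dims[2] < 2L) {
    abort("Trials need at least 2 samples.",
          class = "cssdelm_validation_error")
  }
  labels <- validate_labels(labels, length(trials))
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a single positive number.",
          class = "cssdelm_validation_error")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dims[1]))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dims[1] || anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique and match the channel count.",
          class = "cssdelm_validation_error")
  }
  structure(
    list(trials = trials, labels = labels,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_names = channel_names),
    class = "epoched_recording")
}

validate_labels <- function(labels, n_trials) {
  if (length(labels) != n_trials) {
    abort(sprintf("Got %d labels for %d trials.", length(labels), n_trials),
          class = "cssdelm_validation_error")
  }
  bad <- which(!(labels %in% c(1, 2)))
  if (length(bad) > 0) {
    abort(sprintf("Invalid label value %s at position %d; labels must be 1 or 2.",
                  format(labels[bad[1]]), bad[1]),
          class = "cssdelm_validation_error")
  }
  as.integer(labels)
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf(
    "<epoched_recording> %d trials (%d / %d per class), %d channels x %d samples @ %g Hz\n",
    n_trials(x), sum(x$labels == 1L), sum(x$labels == 2L),
    n_channels(x), samples_per_trial(x), x$sampling_rate_hz))
  invisible(x)
}

#' Dimensions of an epoched recording
#'
#' @param recording an [epoched_recording()].
#' @return A single integer.
#' @export
n_trials <- function(recording) length(recording$trials)

#' @rdname n_trials
#' @export
n_channels <- function(recording) length(recording$channel_names)

#' @rdname n_trials
#' @export
samples_per_trial <- function(recording) {
  if (n_trials(recording) == 0L) 0L else ncol(recording$trials[[1L]])
}

#' Partition a recording by imagery class
#'
#' Splits the labelled trials into the two task conditions (class 1 = task A,
#' class 2 = task B). Both classes must be present.
#'
#' @param recording an [epoched_recording()].
#' @return An object of class `class_split`: list with `class_a` and
#'   `class_b`, each a list of trial matrices, plus the originating indices.
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 3, seed = 1))
#' sp <- split_by_class(rec)
#' length(sp$class_a)
#' @export
split_by_class <- function(recording) {
  stopifnot(inherits(recording, "epoched_recording"))
  idx_a <- which(recording$labels == 1L)
  idx_b <- which(recording$labels == 2L)
  if (length(idx_a) == 0L) {
    abort("Class 1 has no trials; both classes are required.",
          class = "cssdelm_validation_error")
  }
  if (length(idx_b) == 0L) {
    abort("Class 2 has no trials; both classes are required.",
          class = "cssdelm_validation_error")
  }
  structure(
    list(class_a = recording$trials[idx_a],
         class_b = recording$trials[idx_b],
         idx_a = idx_a, idx_b = idx_b),
    class = "class_split")
}

#' Keep a subset of channels
#'
#' Slices every trial to the requested channels, in the requested order.
#' Labels and sampling rate are unchanged.
#'
#' @param recording an [epoched_recording()].
#' @param selected integer vector of 1-based channel indices (order kept).
#' @return An [epoched_recording()] with `length(selected)` channels.
#' @export
restrict_channels <- function(recording, selected) {
  stopifnot(inherits(recording, "epoched_recording"))
  selected <- as.integer(selected)
  nc <- n_channels(recording)
  if (length(selected) < 1L || any(selected < 1L) || any(selected > nc)) {
    abort(sprintf("Channel indices must lie in 1..%d.", nc),
          class = "cssdelm_validation_error")
  }
  if (anyDuplicated(selected)) {
    abort("Duplicate channel indices in `selected`.",
          class = "cssdelm_validation_error")
  }
  epoched_recording(
    trials = lapply(recording$trials, function(tr) tr[selected, , drop = FALSE]),
    labels = recording$labels,
    sampling_rate_hz = recording$sampling_rate_hz,
    channel_names = recording$channel_names[selected])
}

# One-of-two target coding: class 1 -> (+1, -1), class 2 -> (-1, +1).
# Decoding is the argmax of the two output scores; exact ties go to class 1.
encode_labels <- function(labels) {
  t(vapply(labels, function(l) if (l == 1L) c(1, -1) else c(-1, 1),
           numeric(2)))
}

decode_scores <- function(scores) {
  scores <- as.matrix(scores)
  ifelse(scores[, 1L] >= scores[, 2L], 1L, 2L)
}
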