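# broom-style tidiers for the package's fitted objects

#' Tidy a channel ranking
#'
#' @param x a `channel_ranking`.
#' @param ... unused.
#' @return A plain tibble: `channel`, `channel_name`, `h`, `rank`,
#'   `selected`, sorted by rank.
#' @export
tidy.channel_ranking <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "channel_ranking")
  dplyr::arrange(out, .data$rank)
}

#' Tidy a CSSD filter bank
#'
#' One row per retained whitened-space component with its class-A and
#' class-B eigenvalues (variance fractions; the two always sum to 1) and
#' which bank, if any, uses the component.
#'
#' @param x a `spatial_filter_bank`.
#' @param ... unused.
#' @return A tibble: `component`, `eigval_a`, `eigval_b`, `in_bank`.
#' @export
tidy.spatial_filter_bank <- function(x, ...) {
  r <- x$rank
  in_a <- seq_len(r) <= x$J
  in_b <- seq_len(r) > r - x$J
  tibble(component = seq_len(r),
         eigval_a = x$eigvals_a, eigval_b = x$eigvals_b,
         in_bank = dplyr::case_when(in_a & in_b ~ "both",
                                    in_a ~ "A", in_b ~ "B",
                                    TRUE ~ "none"))
}

#' @rdname tidy.spatial_filter_bank
#' @export
glance.spatial_filter_bank <- function(x, ...) {
  tibble(J = x$J, rank = x$rank, n_channels = length(x$channel_names),
         top_eigval_a = x$eigvals_a[1L],
         top_eigval_b = max(x$eigvals_b))
}

#' Tidy a kernel-ELM model
#'
#' @param x an `elm_kernel_model`.
#' @param ... unused.
#' @return A tibble with one row per training point: `point`, `alpha_1`,
#'   `alpha_2` (dual coefficients for the two output units).
#' @export
tidy.elm_kernel_model <- function(x, ...) {
  tibble(point = seq_len(nrow(x$alpha)),
         alpha_1 = x$alpha[, 1L], alpha_2 = x$alpha[, 2L])
}

#' @rdname tidy.elm_kernel_model
#' @export
glance.elm_kernel_model <- function(x, ...) {
  tibble(n_train = nrow(x$train_features),
         n_features = ncol(x$train_features),
         C = x$C, kernel = x$kernel, gamma = x$gamma)
}

#' Tidy a basic ELM model
#'
#' @param x an `elm_model`.
#' @param ... unused.
#' @return A tibble with one row per hidden node: `node`, `bias`,
#'   `beta_1`, `beta_2`.
#' @export
tidy.elm_model <- function(x, ...) {
  tibble(node = seq_along(x$biases), bias = x$biases,
         beta_1 = x$output_weights[, 1L],
         beta_2 = x$output_weights[, 2L])
}

#' @rdname tidy.elm_model
#' @export
glance.elm_model <- function(x, ...) {
  tibble(n_hidden = length(x$biases), n_features = x$n_features,
         activation = x$activation, seed = x$seed)
}

#' Tidy an evaluation report
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return The confusion tibble (`truth`, `predicted`, `n`).
#' @export
tidy.evaluation_report <- function(x, ...) x$confusion

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         accuracy_class_1 = x$per_class_accuracy[["class_1"]],
         accuracy_class_2 = x$per_class_accuracy[["class_2"]],
         n_train = x$n_train, n_test = x$n_test, seed = x$seed)
}

#' Tidy a fitted pipeline
#'
#' @param x a `trained_pipeline`.
#' @param ... unused.
#' @return The training-time channel ranking as a tibble.
#' @export
tidy.trained_pipeline <- function(x, ...) tidy(x$ranking)

#' @rdname tidy.trained_pipeline
#' @export
glance.trained_pipeline <- function(x, ...) {
  tibble(classifier = x$config$classifier,
         n_channels_selected = length(x$selected_names),
         J = x$bank$J, n_features = 2L * x$bank$J,
         n_train = x$n_train, seed = x$config$seed,
         fingerprint = x$fingerprint)
}
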