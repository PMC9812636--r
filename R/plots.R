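# ggplot2 autoplot methods for each result type

#' Plot a channel ranking
#'
#' Bar chart of the relative distance h per channel, selected channels
#' highlighted.
#'
#' @param object a `channel_ranking`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.channel_ranking <- function(object, ...) {
  df <- tidy(object)
  df$channel_name <- factor(df$channel_name,
                            levels = df$channel_name[order(df$channel)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_name, y = .data$h,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(x = "channel", y = "relative distance h(k)",
                  fill = "selected",
                  title = "Per-channel class contrast in mu-band power") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a CSSD eigenvalue spectrum
#'
#' Class-A and class-B eigenvalues of the whitened covariances per
#' component; the two curves mirror each other about 0.5 because they sum
#' to 1.
#'
#' @param object a `spatial_filter_bank`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_filter_bank <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("eigval_a", "eigval_b"),
                            names_to = "class", values_to = "eigenvalue")
  df$class <- ifelse(df$class == "eigval_a", "class 1 (A)", "class 2 (B)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue,
                                   colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(title = "Whitened class-variance spectrum",
                  subtitle = sprintf("J = %d filters per bank", object$J),
                  x = "component", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot features in the best discriminative plane
#'
#' Scatter of the first feature of each bank block, coloured by class.
#'
#' @param object a `feature_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.feature_matrix <- function(object, ...) {
  J <- attr(object, "J") %||% (sum(grepl("^f[0-9]+$", names(object))) %/% 2L)
  xa <- "f01"
  xb <- sprintf("f%02d", J + 1L)
  df <- as_tibble(object)
  df$class <- factor(df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xa]], y = .data[[xb]],
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = "Normalized log-variance features",
                  x = "first A-bank feature", y = "first B-bank feature") +
    ggplot2::theme_minimal()
}

#' Plot a filter-count sweep
#'
#' @param object a [sweep_eigenvalues()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cssdelm_sweep_j <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), is.na(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$J, y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "Accuracy vs number of spatial filters",
                  x = "J (filters per class bank)", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a training-fraction sweep
#'
#' @param object a [sweep_train_fraction()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cssdelm_sweep_fraction <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), is.na(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                   y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy),
      alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "Accuracy vs training fraction",
                  x = "training fraction", y = "mean test accuracy") +
    ggplot2::theme_minimal()
}
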