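#' Train a basic extreme learning machine
#'
#' An ELM is a single-hidden-layer feed-forward network whose hidden-layer
#' weights and biases are drawn at random and never trained; only the
#' output weights are fitted, in closed form, as the minimal-norm
#' least-squares solution `beta = pinv(H) T` where `H` is the hidden-layer
#' output matrix (sigmoid activation) and `T` the one-of-two target matrix
#' (class 1 -> `(+1, -1)`, class 2 -> `(-1, +1)`).
#'
#' @param features a `feature_matrix` tibble (needs a `label` column), or
#'   anything [featurize_recording()] produces.
#' @param n_hidden number of hidden nodes (default 100).
#' @param seed integer seed for the hidden layer draw; the same seed gives
#'   a bit-identical model.
#' @return An object of class `elm_model` with elements `input_weights`
#'   (`n_hidden x d`, uniform on `[-1, 1]`), `biases`, `output_weights`
#'   (`n_hidden x 2`), `activation`, `seed`.
#' @examples
#' feats <- demo_features(seed = 1)
#' fit <- train_elm(feats, n_hidden = 50, seed = 1)
#' accuracy(predict(fit, feats)$label, feats$label)
#' @export
train_elm <- function(features, n_hidden = 100L, seed = 1L) {
  xy <- feature_xy(features)
  check_training_set(xy)
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) abort("n_hidden must be >= 1.",
                           class = "cssdelm_config_error")
  d <- ncol(xy$x)
  wb <- withr::with_seed(as.integer(seed), {
    list(w = matrix(runif(n_hidden * d, -1, 1), n_hidden, d),
         b = runif(n_hidden, -1, 1))
  })
  H <- hidden_layer(xy$x, wb$w, wb$b)
  beta <- pinv_solve(H, encode_labels(xy$y))
  structure(list(input_weights = wb$w, biases = wb$b, output_weights = beta,
                 activation = "sigmoid", seed = as.integer(seed),
                 n_features = d),
            class = "elm_model")
}

hidden_layer <- function(x, w, b) {
  z <- x %*% t(w)
  z <- sweep(z, 2L, b, `+`)
  1 / (1 + exp(-z))
}

# minimal-norm least-squares via thin SVD (Moore-Penrose solve)
pinv_solve <- function(a, b) {
  sv <- svd(a)
  tol <- max(dim(a)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(a), ncol(b)))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

check_training_set <- function(xy) {
  if (is.null(xy$y)) {
    abort("Training features need a `label` column.",
          class = "cssdelm_validation_error")
  }
  if (nrow(xy$x) < 2L || length(unique(xy$y)) < 2L) {
    abort("Training needs at least two trials with both classes present.",
          class = "cssdelm_validation_error")
  }
}

#' Predict imagery class with a trained ELM
#'
#' @param object an `elm_model`.
#' @param features feature tibble or numeric matrix (rows = trials).
#' @param ... unused.
#' @return A tibble with columns `label` (argmax of the two output scores,
#'   ties to class 1), `score_1`, `score_2`.
#' @export
predict.elm_model <- function(object, features, ...) {
  x <- feature_xy(features)$x
  if (ncol(x) != object$n_features) {
    abort(sprintf("Features have %d columns; the model expects %d.",
                  ncol(x), object$n_features),
          class = "cssdelm_validation_error")
  }
  scores <- hidden_layer(x, object$input_weights, object$biases) %*%
    object$output_weights
  tibble(label = decode_scores(scores),
         score_1 = scores[, 1L], score_2 = scores[, 2L])
}

#' Train a kernel extreme learning machine
#'
#' The kernel variant replaces the random hidden layer with a Mercer
#' kernel and solves, in closed form,
#' `alpha = (I/C + K)^{-1} T`
#' where `K` is the training kernel matrix, `C` the regularization factor
#' trading training fit against solution norm, and `T` the one-of-two
#' target matrix. A new point `x` is scored as `k(x, X_train) alpha`. This
#' is exactly kernel ridge regression with ridge `1/C` on the `(+1, -1)`
#' targets; unlike the basic ELM it involves no randomness, which is why
#' its accuracy is stable across repetitions. The solve uses a Cholesky
#' factorization of the symmetric positive-definite system, never an
#' explicit inverse.
#'
#' @param features a `feature_matrix` tibble with a `label` column.
#' @param C regularization factor, `> 0` (default 10).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width in `exp(-gamma ||x - y||^2)`. Default
#'   `"median"`: `1 / (2 m^2)` with `m` the median pairwise training
#'   distance — a scale-free heuristic.
#' @return An object of class `elm_kernel_model` with `train_features`,
#'   `alpha` (`N x 2`), `C`, `kernel`, `gamma`.
#' @examples
#' feats <- demo_features(seed = 1)
#' fit <- train_elm_kernel(feats, C = 10)
#' accuracy(predict(fit, feats)$label, feats$label)
#' @export
train_elm_kernel <- function(features, C = 10, kernel = c("rbf", "linear"),
                             gamma = "median") {
  kernel <- match.arg(kernel)
  xy <- feature_xy(features)
  check_training_set(xy)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    abort("C must be a single positive number.",
          class = "cssdelm_config_error")
  }
  if (identical(gamma, "median")) {
    gamma <- median_gamma(xy$x)
  } else if (!is.numeric(gamma) || gamma <= 0) {
    abort("gamma must be positive (or \"median\").",
          class = "cssdelm_config_error")
  }
  K <- kernel_matrix(xy$x, xy$x, kernel, gamma)
  A <- K + diag(1 / C, nrow(K))
  R <- tryCatch(chol(A), error = function(e) {
    abort("Kernel system is not positive definite; increase C or check features.",
          class = "cssdelm_computation_error")
  })
  alpha <- backsolve(R, forwardsolve(t(R), encode_labels(xy$y)))
  structure(list(train_features = xy$x, alpha = alpha, C = C,
                 kernel = kernel, gamma = gamma),
            class = "elm_kernel_model")
}

median_gamma <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) return(1)
  1 / (2 * m^2)
}

kernel_matrix <- function(x, y, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(x, y))
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(d2, 0))
}

#' Predict imagery class with a trained kernel ELM
#'
#' @param object an `elm_kernel_model`.
#' @param features feature tibble or numeric matrix (rows = trials).
#' @param ... unused.
#' @return A tibble with columns `label`, `score_1`, `score_2`.
#' @export
predict.elm_kernel_model <- function(object, features, ...) {
  x <- feature_xy(features)$x
  if (ncol(x) != ncol(object$train_features)) {
    abort(sprintf("Features have %d columns; the model expects %d.",
                  ncol(x), ncol(object$train_features)),
          class = "cssdelm_validation_error")
  }
  scores <- kernel_matrix(x, object$train_features, object$kernel,
                          object$gamma) %*% object$alpha
  tibble(label = decode_scores(scores),
         score_1 = scores[, 1L], score_2 = scores[, 2L])
}

#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors in `{1, 2}`.
#' @return Proportion of agreements, in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort("Label vectors must be nonempty and of equal length.",
          class = "cssdelm_validation_error")
  }
  mean(predicted == truth)
}

#' Small separable demo feature set
#'
#' Two Gaussian blobs in feature space, handy for examples and quick
#' classifier checks.
#'
#' @param n_per_class trials per class.
#' @param d feature dimension.
#' @param separation distance between class means in units of the
#'   within-class standard deviation.
#' @param seed integer seed.
#' @return A `feature_matrix`-shaped tibble with `trial`, `label`,
#'   `f01...`.
#' @export
demo_features <- function(n_per_class = 20L, d = 4L, separation = 4,
                          seed = 1L) {
  withr::with_seed(as.integer(seed), {
    x <- rbind(
      matrix(rnorm(n_per_class * d), n_per_class, d),
      matrix(rnorm(n_per_class * d, mean = separation / sqrt(d)),
             n_per_class, d))
    colnames(x) <- sprintf("f%02d", seq_len(d))
    out <- dplyr::bind_cols(
      tibble(trial = seq_len(2L * n_per_class),
             label = rep(1:2, each = n_per_class)),
      as_tibble(x))
    class(out) <- c("feature_matrix", class(out))
    out
  })
}
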