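#' Trace-normalized spatial covariance of one trial
#'
#' For a trial `X` (channels x samples) the normalized covariance is
#' `R = X X' / trace(X X')`, so every trial contributes on the same scale
#' regardless of its amplitude. The result is symmetric, positive
#' semidefinite, with trace exactly 1.
#'
#' @param trial numeric matrix, channels x samples.
#' @return Symmetric `n x n` matrix with unit trace.
#' @examples
#' trial_covariance(diag(2))   # I / 2
#' @export
trial_covariance <- function(trial) {
  trial <- as.matrix(trial)
  cp <- tcrossprod(trial)
  tr <- sum(diag(cp))
  if (!is.finite(tr) || tr <= 0) {
    abort("Trial has zero (or non-finite) power; covariance normalization undefined.",
          class = "cssdelm_validation_error")
  }
  cp / tr
}

#' Class covariance: mean of per-trial normalized covariances
#'
#' Averaging trace-normalized per-trial covariances (rather than pooling
#' samples) keeps high-amplitude trials from dominating the estimate —
#' standard practice for CSP-family spatial filtering.
#'
#' @param trials list of trial matrices from one class.
#' @param class_label optional class tag (1 or 2) carried on the result.
#' @return An object of class `class_covariance`: list with `matrix`
#'   (symmetric PSD, unit trace), `class_label`, `n_trials_used`.
#' @export
class_covariance <- function(trials, class_label = NULL) {
  if (!is.list(trials) || length(trials) == 0L) {
    abort("Need at least one trial.", class = "cssdelm_validation_error")
  }
  acc <- Reduce(`+`, lapply(trials, trial_covariance)) / length(trials)
  acc <- (acc + t(acc)) / 2  # enforce exact symmetry
  structure(list(matrix = acc, class_label = class_label,
                 n_trials_used = length(trials)),
            class = "class_covariance")
}

as_cov_matrix <- function(x, arg = "covariance") {
  m <- if (inherits(x, "class_covariance")) x$matrix else as.matrix(x)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort(sprintf("`%s` must be a symmetric square matrix.", arg),
          class = "cssdelm_validation_error")
  }
  (m + t(m)) / 2
}

#' Fit CSSD spatial filter banks by whitening and simultaneous diagonalization
#'
#' Common spatial subspace decomposition builds two class-specific filter
#' banks from the class covariances `R_A`, `R_B`:
#'
#' 1. Eigendecompose the summed covariance `R = R_A + R_B = U S U'` and
#'    form the whitening matrix `P = S^{-1/2} U'`, so `P R P' = I`.
#'    Eigenvalues below `1e-10` of the largest are dropped, so `P` maps
#'    onto the effective rank-`r` subspace.
#' 2. Whiten one class: `S_A = P R_A P' = U_A D_A U_A'`. Because
#'    `S_A + S_B = I`, both whitened covariances share eigenvectors and
#'    their eigenvalues are complementary (`D_A + D_B = I`): a direction
#'    with large class-A variance has small class-B variance and vice
#'    versa.
#' 3. Keep the eigenvectors of the `J` largest eigenvalues of each class
#'    (`W_A` for A; for B the same vectors ordered by `1 - D_A`) and map
#'    them back through the whitening: `SF_A = W_A' P`, `SF_B = W_B' P`,
#'    each `J x n`.
#'
#' Eigenvector signs are fixed so each vector's largest-magnitude entry is
#' positive, making the fit deterministic across linear-algebra backends.
#'
#' @param cov_a,cov_b class covariances ([class_covariance()] objects or
#'   plain symmetric matrices) for class 1 and class 2.
#' @param J number of spatial filters per class bank (default 10, giving
#'   `2J = 20` features per trial).
#' @param channel_names optional channel order the bank expects.
#' @return An object of class `spatial_filter_bank`: list with `whitening`
#'   (`r x n`), `eigvals_a` (descending), `eigvals_b` (`= 1 - eigvals_a`,
#'   same eigenvector order), `filters_a`, `filters_b` (`J x n`), `J`,
#'   `rank`, `channel_names`.
#' @examples
#' ra <- diag(c(0.9, 0.1)); rb <- diag(c(0.1, 0.9))
#' bank <- fit_cssd(ra, rb, J = 1)
#' bank$eigvals_a
#' @export
fit_cssd <- function(cov_a, cov_b, J = 10L, channel_names = NULL) {
  ra <- as_cov_matrix(cov_a, "cov_a")
  rb <- as_cov_matrix(cov_b, "cov_b")
  if (!identical(dim(ra), dim(rb))) {
    abort("cov_a and cov_b must have identical dimensions.",
          class = "cssdelm_validation_error")
  }
  n <- nrow(ra)
  J <- as.integer(J)
  if (J < 1L) abort("J must be >= 1.", class = "cssdelm_config_error")

  r_sum <- ra + rb
  es <- eigen(r_sum, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  r <- sum(keep)
  if (J > r) {
    abort(sprintf("J = %d exceeds the effective rank %d of R_A + R_B.", J, r),
          class = "cssdelm_config_error")
  }
  P <- diag(1 / sqrt(es$values[keep]), r) %*% t(es$vectors[, keep, drop = FALSE])

  s_a <- P %*% ra %*% t(P)
  s_a <- (s_a + t(s_a)) / 2
  ea <- eigen(s_a, symmetric = TRUE)       # eigenvalues descending
  U <- apply(ea$vectors, 2L, fix_sign)
  if (r == 1L) U <- matrix(U, 1L, 1L)
  lam_a <- ea$values
  lam_b <- 1 - lam_a                       # complementarity of whitened covs

  w_a <- U[, seq_len(J), drop = FALSE]
  ord_b <- order(lam_b, decreasing = TRUE) # = reverse order of lam_a
  w_b <- U[, ord_b[seq_len(J)], drop = FALSE]

  structure(
    list(whitening = P, eigvals_a = lam_a, eigvals_b = lam_b,
         filters_a = t(w_a) %*% P, filters_b = t(w_b) %*% P,
         J = J, rank = r,
         channel_names = channel_names %||% sprintf("ch%02d", seq_len(n))),
    class = "spatial_filter_bank")
}

fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf(
    "<spatial_filter_bank> J = %d filters/class over %d channels (rank %d)\n",
    x$J, ncol(x$filters_a), x$rank))
  cat("  top class-A eigenvalues:",
      paste(sprintf("%.3f", head(x$eigvals_a, 5L)), collapse = " "), "\n")
  invisible(x)
}

#' Normalized log-variance features of one trial
#'
#' Projects the trial through both filter banks and summarises each
#' filtered component by its log variance, normalized within the bank:
#' `v'_j = log(var(v_j) / sum_j var(v_j))`. The feature vector is the
#' concatenation `[A-bank block, B-bank block]`, length `2J`; within each
#' block `sum_j exp(v'_j) = 1` and every entry is `<= 0`. Both banks are
#' applied because a test trial's class is unknown, so its features must
#' not depend on a label.
#'
#' @param trial channels x samples matrix, channel order matching
#'   `bank$channel_names`.
#' @param bank a [fit_cssd()] bank.
#' @return Numeric vector of length `2J`.
#' @export
extract_features <- function(trial, bank) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  trial <- as.matrix(trial)
  nch <- ncol(bank$filters_a)
  if (nrow(trial) != nch) {
    abort(sprintf("Trial has %d channels; the filter bank expects %d.",
                  nrow(trial), nch),
          class = "cssdelm_validation_error")
  }
  c(log_var_block(bank$filters_a %*% trial),
    log_var_block(bank$filters_b %*% trial))
}

# population variances of the filtered rows, normalized then logged
log_var_block <- function(y) {
  mu <- rowMeans(y)
  v <- rowMeans((y - mu)^2)
  v <- pmax(v, 1e-300)  # floor keeps log finite while preserving order
  log(v / sum(v))
}

#' Featurize every trial of a recording
#'
#' Applies [extract_features()] per trial and returns the feature matrix in
#' tidy form.
#'
#' @param recording an [epoched_recording()] (channel order must match the
#'   bank).
#' @param bank a [fit_cssd()] bank.
#' @return A `feature_matrix`: tibble with columns `trial`, `label` and
#'   `f01 ... f<2J>`; attributes `J` and `bank_fingerprint`.
#' @export
featurize_recording <- function(recording, bank) {
  stopifnot(inherits(recording, "epoched_recording"),
            inherits(bank, "spatial_filter_bank"))
  if (n_trials(recording) == 0L) {
    fm <- matrix(numeric(0), 0L, 2L * bank$J,
                 dimnames = list(NULL, sprintf("f%02d", seq_len(2L * bank$J))))
    out <- dplyr::bind_cols(tibble(trial = integer(0), label = integer(0)),
                            as_tibble(fm))
    attr(out, "J") <- bank$J
    attr(out, "bank_fingerprint") <- rlang::hash(bank)
    class(out) <- c("feature_matrix", class(out))
    return(out)
  }
  feats <- lapply(seq_len(n_trials(recording)), function(k) {
    tryCatch(extract_features(recording$trials[[k]], bank),
             error = function(e) {
               abort(sprintf("Feature extraction failed on trial %d: %s",
                             k, conditionMessage(e)),
                     class = "cssdelm_validation_error")
             })
  })
  fm <- do.call(rbind, feats)
  colnames(fm) <- sprintf("f%02d", seq_len(2L * bank$J))
  out <- dplyr::bind_cols(
    tibble(trial = seq_len(n_trials(recording)),
           label = recording$labels),
    as_tibble(fm))
  attr(out, "J") <- bank$J
  attr(out, "bank_fingerprint") <- rlang::hash(bank)
  class(out) <- c("feature_matrix", class(out))
  out
}

# split a feature tibble (or plain matrix) into X / labels
feature_xy <- function(features) {
  if (inherits(features, "data.frame")) {
    cols <- grep("^f[0-9]+$", names(features), value = TRUE)
    if (length(cols) == 0L) {
      abort("No feature columns (f01, f02, ...) found.",
            class = "cssdelm_validation_error")
    }
    x <- as.matrix(features[, cols, drop = FALSE])
    y <- if ("label" %in% names(features)) as.integer(features$label) else NULL
  } else {
    x <- as.matrix(features)
    y <- NULL
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Features contain non-finite values.",
          class = "cssdelm_validation_error")
  }
  list(x = x, y = y)
}
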