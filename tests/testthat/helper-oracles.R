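# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as plain scalar loops / direct formula
# evaluations, sharing no code with the package internals they check.

# one-sided FFT power of a single channel, summed over [lo, hi] Hz
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}

# straight-line reimplementation of the normalized log-variance features:
# project, per-row population variance, normalize within bank, log
oracle_features <- function(trial, sf_a, sf_b) {
  block <- function(sf) {
    J <- nrow(sf)
    v <- numeric(J)
    for (j in seq_len(J)) {
      y <- as.numeric(sf[j, , drop = FALSE] %*% trial)
      m <- sum(y) / length(y)
      v[j] <- sum((y - m)^2) / length(y)
    }
    out <- numeric(J)
    for (j in seq_len(J)) out[j] <- log(v[j] / sum(v))
    out
  }
  c(block(sf_a), block(sf_b))
}

# independently coded kernel ridge regression: explicit loop kernel,
# generic solve() of (K + lambda I) alpha = T
oracle_krr <- function(x, targets, C, gamma = NULL, kernel = "rbf") {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- if (kernel == "linear") {
        sum(x[i, ] * x[j, ])
      } else {
        exp(-gamma * sum((x[i, ] - x[j, ])^2))
      }
    }
  }
  solve(K + diag(1 / C, n), targets)
}

# random symmetric PSD covariance with unit trace (a plausible class cov)
random_psd_cov <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * (n + 2)), n)
  m <- tcrossprod(a)
  m / sum(diag(m))
}

# white-noise recording of the given shape, balanced labels
white_recording <- function(n_trials = 10, n_channels = 4, ns = 200,
                            fs = 250, seed = 1) {
  withr::with_seed(seed, {
    trials <- replicate(n_trials,
                        matrix(rnorm(n_channels * ns), n_channels, ns),
                        simplify = FALSE)
    epoched_recording(trials, rep_len(c(1L, 2L), n_trials), fs)
  })
}

# one-trial recording from a deterministic signal on each channel
signal_trial <- function(freq_hz, fs = 250, ns = 500, amp = 1) {
  tt <- seq_len(ns) / fs
  amp * sin(2 * pi * freq_hz * tt)
}

# fast default-shaped generator config for tests that don't need 50 trials
small_config <- function(...) {
  synthetic_config(n_trials_per_class = 15L, ...)
}

# pipeline config sized for quick fits on small synthetic data
quick_pipeline <- function(...) {
  pipeline_config(channels_m = 12L, J = 4L, ar_order = 10L, ...)
}
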