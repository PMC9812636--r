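#' Class-conditional power spectral density estimate
#'
#' Estimates a per-channel PSD for one class's trials, averaged across the
#' class's trials (averaging per-trial spectra is robust to inter-trial
#' phase discontinuities). Two estimators are available:
#'
#' * `"burg_ar"` — Burg autoregressive spectrum per channel and trial
#'   (default order 16), evaluated on a regular frequency grid. AR spectra
#'   are the field's usual choice for short motor-imagery epochs because
#'   they stay smooth at low sample counts.
#' * `"welch"` — windowed-segment periodogram average (Hann window,
#'   segments of `samples/4`, 50% overlap).
#'
#' @param trials list of `n_channels x samples` trial matrices, all one
#'   class, already band-pass filtered.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param method `"burg_ar"` or `"welch"`.
#' @param ar_order Burg AR model order (burg_ar only).
#' @param freq_step_hz grid step for the AR spectrum, default 0.5 Hz.
#' @param segment_samples Welch segment length; default `samples %/% 4`.
#' @param class_label optional class tag carried on the result.
#' @param channel_names optional channel identifiers.
#' @return An object of class `spectral_profile`: list with
#'   `frequencies_hz` (strictly increasing grid up to Nyquist), `power`
#'   (`n_channels x n_freq`, nonnegative, units power per Hz), `method`,
#'   `method_params`, `n_trials`, `class_label`, `channel_names`.
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 5, seed = 2))
#' sp <- split_by_class(bandpass(rec))
#' psd <- estimate_psd(sp$class_a, rec$sampling_rate_hz)
#' @export
estimate_psd <- function(trials, sampling_rate_hz,
                         method = c("burg_ar", "welch"),
                         ar_order = 16L, freq_step_hz = 0.5,
                         segment_samples = NULL,
                         class_label = NULL, channel_names = NULL) {
  method <- match.arg(method)
  if (!is.list(trials) || length(trials) == 0L) {
    abort("Need at least one trial.", class = "cssdelm_validation_error")
  }
  nc <- nrow(trials[[1L]])
  ns <- ncol(trials[[1L]])
  fs <- sampling_rate_hz
  if (method == "burg_ar") {
    if (ar_order >= ns) {
      abort(sprintf("AR order (%d) must be below samples per trial (%d).",
                    ar_order, ns),
            class = "cssdelm_config_error")
    }
    freqs <- seq(0, fs / 2, by = freq_step_hz)
    params <- list(ar_order = as.integer(ar_order),
                   freq_step_hz = freq_step_hz)
  } else {
    if (is.null(segment_samples)) segment_samples <- max(8L, ns %/% 4L)
    segment_samples <- as.integer(segment_samples)
    if (segment_samples > ns) {
      abort("Welch segment length exceeds samples per trial.",
            class = "cssdelm_config_error")
    }
    freqs <- seq(0L, segment_samples %/% 2L) * fs / segment_samples
    params <- list(segment_samples = segment_samples, overlap = 0.5)
  }
  acc <- matrix(0, nc, length(freqs))
  for (tr in trials) {
    for (ch in seq_len(nc)) {
      acc[ch, ] <- acc[ch, ] + switch(method,
        burg_ar = psd_burg(tr[ch, ], fs, ar_order, freqs),
        welch   = psd_welch(tr[ch, ], fs, segment_samples))
    }
  }
  structure(
    list(frequencies_hz = freqs, power = acc / length(trials),
         method = method, method_params = params,
         n_trials = length(trials), class_label = class_label,
         channel_names = channel_names),
    class = "spectral_profile")
}

# Burg AR spectrum: sigma^2 / (fs * |1 - sum_k a_k e^{-2 pi i f k / fs}|^2)
psd_burg <- function(x, fs, order, freqs) {
  if (all(x == 0)) return(rep(0, length(freqs)))
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  k <- seq_along(a)
  denom <- vapply(freqs, function(f) {
    e <- exp(-2i * pi * f * k / fs)
    Mod(1 - sum(a * e))^2
  }, numeric(1))
  as.numeric(fit$var.pred / (fs * denom))
}

# Hann-windowed 50%-overlap segment periodogram average (one-sided density)
psd_welch <- function(x, fs, seg) {
  n <- length(x)
  hop <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / seg)
  scale <- fs * sum(w^2)
  nf <- seg %/% 2L + 1L
  p <- numeric(nf)
  for (s in starts) {
    segx <- x[s:(s + seg - 1L)]
    X <- stats::fft((segx - mean(segx)) * w)
    pxx <- Mod(X[seq_len(nf)])^2 / scale
    # fold the two-sided spectrum into one side (not DC/Nyquist)
    if (nf > 2L) pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
    p <- p + pxx
  }
  p / length(starts)
}
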