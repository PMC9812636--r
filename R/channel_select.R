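#' Rank channels by the relative-distance criterion
#'
#' ERD is expressed over a small set of task-relevant sensors, so channels
#' differ in how much their spectra separate the two imagery classes. The
#' relative distance of channel k is the normalized class contrast in
#' mu-band (default 8-13 Hz) power:
#'
#' \deqn{h(k) = \frac{|\sum_{f \in f_T} P_{1,k}(f) - \sum_{f \in f_T} P_{2,k}(f)|}
#'                   {\sum_{f \in f_T} P_{1,k}(f) + \sum_{f \in f_T} P_{2,k}(f)}}
#'
#' with sums over the grid points inside the band, so `h` lies in `[0, 1]`:
#' 0 when the class spectra agree on the channel, 1 when one class carries
#' all the band power. Larger `h` means a larger contribution to
#' classification.
#'
#' @param profile_a,profile_b [estimate_psd()] profiles for class 1 and
#'   class 2, sharing frequency grid and channel count.
#' @param band numeric length-2, the scoring band in Hz (default mu band
#'   `c(8, 13)`).
#' @return A `channel_ranking`: a tibble with columns `channel` (original
#'   1-based index), `channel_name`, `h`, `rank` (1 = largest `h`, ties
#'   broken toward the lower original index) and `selected` (logical; all
#'   `FALSE` until [select_channels()] is applied).
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 10, seed = 3))
#' rk <- rank_channels(bandpass(rec))
#' head(tidy(rk))
#' @export
relative_distance <- function(profile_a, profile_b, band = c(8, 13)) {
  stopifnot(inherits(profile_a, "spectral_profile"),
            inherits(profile_b, "spectral_profile"))
  if (!isTRUE(all.equal(profile_a$frequencies_hz, profile_b$frequencies_hz))) {
    abort("The two profiles must share one frequency grid.",
          class = "cssdelm_validation_error")
  }
  if (nrow(profile_a$power) != nrow(profile_b$power)) {
    abort("The two profiles must cover the same channels.",
          class = "cssdelm_validation_error")
  }
  freqs <- profile_a$frequencies_hz
  in_band <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(in_band)) {
    abort(sprintf("No grid points inside the band [%g, %g] Hz.",
                  band[1L], band[2L]),
          class = "cssdelm_config_error")
  }
  s1 <- rowSums(profile_a$power[, in_band, drop = FALSE])
  s2 <- rowSums(profile_b$power[, in_band, drop = FALSE])
  tot <- s1 + s2
  h <- ifelse(tot > 0, abs(s1 - s2) / tot, 0)
  if (any(tot == 0)) {
    warn(sprintf("%d channel(s) carry zero band power in both classes; h set to 0.",
                 sum(tot == 0)))
  }
  nc <- length(h)
  nms <- profile_a$channel_names %||% sprintf("ch%02d", seq_len(nc))
  ord <- order(-h, seq_len(nc))
  rk <- integer(nc)
  rk[ord] <- seq_len(nc)
  new_channel_ranking(tibble(
    channel = seq_len(nc), channel_name = nms,
    h = as.numeric(h), rank = rk, selected = FALSE))
}

new_channel_ranking <- function(tbl) {
  class(tbl) <- c("channel_ranking", class(tbl))
  tbl
}

#' Select the top-m channels of a ranking
#'
#' Marks the `m` channels with the largest relative distance as selected
#' (ties broken toward the lower original channel index, so selection is
#' deterministic). The field default keeps 25 channels.
#'
#' @param ranking a `channel_ranking` from [relative_distance()] or
#'   [rank_channels()].
#' @param m number of channels to keep, `1 <= m <= n_channels`.
#' @return The ranking with its `selected` column updated.
#' @export
select_channels <- function(ranking, m = 25L) {
  stopifnot(inherits(ranking, "channel_ranking"))
  nc <- nrow(ranking)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > nc) {
    abort(sprintf("`m` must lie in 1..%d.", nc),
          class = "cssdelm_config_error")
  }
  ranking$selected <- ranking$rank <= m
  ranking
}

#' Channel indices marked selected, best first
#'
#' @param ranking a `channel_ranking`.
#' @return Integer vector of original channel indices in rank order.
#' @export
selected_channels <- function(ranking) {
  stopifnot(inherits(ranking, "channel_ranking"))
  sel <- ranking[ranking$selected, , drop = FALSE]
  sel$channel[order(sel$rank)]
}

#' One-call channel ranking for a labelled recording
#'
#' Splits the recording by class, estimates the class-conditional PSDs and
#' scores every channel by [relative_distance()]. When `m` is given the
#' top-m subset is marked selected.
#'
#' @param recording a band-pass filtered [epoched_recording()] with both
#'   classes present.
#' @param band scoring band in Hz, default `c(8, 13)`.
#' @param m optional subset size passed to [select_channels()].
#' @inheritParams estimate_psd
#' @param ... further arguments passed to [estimate_psd()].
#' @return A `channel_ranking` tibble.
#' @export
rank_channels <- function(recording, band = c(8, 13), m = NULL,
                          method = c("burg_ar", "welch"), ...) {
  method <- match.arg(method)
  sp <- split_by_class(recording)
  pa <- estimate_psd(sp$class_a, recording$sampling_rate_hz, method = method,
                     class_label = 1L,
                     channel_names = recording$channel_names, ...)
  pb <- estimate_psd(sp$class_b, recording$sampling_rate_hz, method = method,
                     class_label = 2L,
                     channel_names = recording$channel_names, ...)
  rk <- relative_distance(pa, pb, band = band)
  if (!is.null(m)) rk <- select_channels(rk, m)
  rk
}
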