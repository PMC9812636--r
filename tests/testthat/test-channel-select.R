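# build a spectral_profile directly from a power matrix
profile_of <- function(power, freqs = seq(0, 125, by = 0.5), label = 1L) {
  structure(list(frequencies_hz = freqs, power = power,
                 method = "burg_ar", method_params = list(),
                 n_trials = 1L, class_label = label, channel_names = NULL),
            class = "spectral_profile")
}

test_that("relative distance evaluates the band-power contrast exactly", {
  freqs <- seq(0, 125, by = 0.5)
  band <- freqs >= 8 & freqs <= 13
  nf <- length(freqs)

  p1 <- matrix(1, 3, nf)
  p2 <- matrix(1, 3, nf)
  # channel 1: identical spectra -> h = 0
  # channel 2: class 2 empty -> h = 1
  p2[2, ] <- 0
  # channel 3: band sums 3 vs 1 -> h = 0.5
  p1[3, ] <- 3 / sum(band)
  p2[3, ] <- 1 / sum(band)
  p1[3, !band] <- 9; p2[3, !band] <- 1  # out-of-band power is ignored

  rk <- relative_distance(profile_of(p1), profile_of(p2, label = 2L))
  expect_equal(rk$h[1], 0)
  expect_equal(rk$h[2], 1)
  expect_equal(rk$h[3], 0.5)
  expect_true(all(rk$h >= 0 & rk$h <= 1))
})

test_that("h is scale-invariant, class-symmetric, permutation-equivariant", {
  withr::local_seed(21)
  nf <- 251
  freqs <- seq(0, 125, by = 0.5)
  p1 <- matrix(rexp(5 * nf), 5, nf)
  p2 <- matrix(rexp(5 * nf), 5, nf)
  h0 <- relative_distance(profile_of(p1), profile_of(p2))$h

  scaled1 <- p1; scaled2 <- p2
  scaled1[3, ] <- 7.5 * p1[3, ]; scaled2[3, ] <- 7.5 * p2[3, ]
  expect_equal(relative_distance(profile_of(scaled1),
                                 profile_of(scaled2))$h, h0,
               tolerance = 1e-12)

  expect_equal(relative_distance(profile_of(p2), profile_of(p1))$h, h0,
               tolerance = 1e-12)

  perm <- c(4, 1, 5, 2, 3)
  hp <- relative_distance(profile_of(p1[perm, ]),
                          profile_of(p2[perm, ]))$h
  expect_equal(hp, h0[perm], tolerance = 1e-12)
})

test_that("zero band power in both classes maps to h = 0 with a warning", {
  freqs <- seq(0, 125, by = 0.5)
  p <- matrix(1, 2, length(freqs))
  p[2, freqs >= 8 & freqs <= 13] <- 0
  expect_warning(rk <- relative_distance(profile_of(p), profile_of(p / 2)),
                 "zero band power")
  expect_equal(rk$h[2], 0)
})

test_that("mismatched grids are rejected", {
  a <- profile_of(matrix(1, 2, 251))
  b <- profile_of(matrix(1, 2, 126), freqs = seq(0, 125, by = 1))
  expect_error(relative_distance(a, b), class = "cssdelm_validation_error")
})

test_that("selection keeps the top-m with deterministic tie-breaking", {
  freqs <- seq(0, 125, by = 0.5)
  nf <- length(freqs)
  p1 <- matrix(1, 4, nf)
  p2 <- matrix(1, 4, nf)
  # h = 0.1, 0.9, 0.5, 0.5 (tie between channels 3 and 4)
  hset <- function(i, h) {
    p1[i, ] <<- (1 + h); p2[i, ] <<- (1 - h)
  }
  hset(1, 0.1); hset(2, 0.9); hset(3, 0.5); hset(4, 0.5)
  rk <- relative_distance(profile_of(p1), profile_of(p2))
  expect_equal(rk$h, c(0.1, 0.9, 0.5, 0.5), tolerance = 1e-12)

  sel2 <- select_channels(rk, 2)
  expect_setequal(selected_channels(sel2), c(2L, 3L))  # tie -> lower index
  expect_equal(selected_channels(sel2)[1], 2L)         # best first

  expect_equal(sort(selected_channels(select_channels(rk, 4))), 1:4)
  expect_error(select_channels(rk, 0), class = "cssdelm_config_error")
  expect_error(select_channels(rk, 5), class = "cssdelm_config_error")
})

test_that("active channels outrank inactive ones on synthetic ERD data", {
  cfg <- synthetic_config(n_trials_per_class = 30, seed = 101)
  rk <- rank_channels(bandpass(simulate_recording(cfg)))
  active <- attr(simulate_recording(cfg), "ground_truth")$active_channels
  expect_gt(mean(rk$h[active]), mean(rk$h[-active]))
})
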