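test_that("trial and class covariances are trace-normalized means", {
  expect_equal(trial_covariance(diag(2)), diag(2) / 2)
  expect_equal(trial_covariance(matrix(c(3, 0), 1, 2)), matrix(1, 1, 1))
  expect_error(trial_covariance(matrix(0, 2, 4)),
               class = "cssdelm_validation_error")

  withr::local_seed(31)
  tr <- matrix(rnorm(3 * 50), 3, 50)
  expect_equal(sum(diag(trial_covariance(tr))), 1, tolerance = 1e-12)

  # identical trials: class covariance equals the single-trial covariance
  cc <- class_covariance(list(tr, tr, tr))
  expect_equal(cc$matrix, trial_covariance(tr), tolerance = 1e-12)
  expect_equal(cc$n_trials_used, 3L)

  # hand average of I/2 and diag(1, 0)
  t1 <- diag(2)                      # covariance I/2
  t2 <- matrix(c(1, 0, 0, 0), 2, 2)  # covariance diag(1, 0)
  expect_equal(class_covariance(list(t1, t2))$matrix,
               diag(c(0.75, 0.25)), tolerance = 1e-12)

  # law of large numbers: white noise covariance approaches I/4
  trials <- replicate(50, matrix(rnorm(4 * 500), 4, 500), simplify = FALSE)
  dev <- class_covariance(trials)$matrix - diag(4) / 4
  expect_lt(sqrt(sum(dev^2)), 0.1)
})

test_that("fit_cssd whitens, diagonalizes both classes, and is complementary", {
  withr::local_seed(32)
  for (n in c(3, 6, 10)) {
    ra <- random_psd_cov(n)
    rb <- random_psd_cov(n)
    bank <- fit_cssd(ra, rb, J = 2)
    P <- bank$whitening
    expect_equal(P %*% (ra + rb) %*% t(P), diag(bank$rank),
                 tolerance = 1e-8)
    expect_equal(bank$eigvals_a + bank$eigvals_b,
                 rep(1, bank$rank), tolerance = 1e-8)
    da <- bank$filters_a %*% ra %*% t(bank$filters_a)
    db <- bank$filters_b %*% rb %*% t(bank$filters_b)
    expect_lt(max(abs(da - diag(diag(da)))), 1e-8)
    expect_lt(max(abs(db - diag(diag(db)))), 1e-8)
    expect_true(all(diff(bank$eigvals_a) <= 1e-12))
  }
})

test_that("equal class covariances give the degenerate all-0.5 spectrum", {
  r <- random_psd_cov(5, seed = 33)
  bank <- fit_cssd(r, r, J = 2)
  expect_equal(bank$eigvals_a, rep(0.5, bank$rank), tolerance = 1e-10)
})

test_that("the 2x2 diagonal example is solved in closed form", {
  bank <- fit_cssd(diag(c(0.9, 0.1)), diag(c(0.1, 0.9)), J = 1)
  expect_equal(bank$eigvals_a[1], 0.9, tolerance = 1e-12)
  # SF_A picks channel 1, SF_B channel 2 (up to scale; sign fixed positive)
  fa <- bank$filters_a / max(abs(bank$filters_a))
  fb <- bank$filters_b / max(abs(bank$filters_b))
  expect_equal(abs(fa), matrix(c(1, 0), 1, 2), tolerance = 1e-10)
  expect_equal(abs(fb), matrix(c(0, 1), 1, 2), tolerance = 1e-10)
})

test_that("rank deficiency is detected and J is bounded by the rank", {
  # two channels carry identical signals -> rank-deficient summed covariance
  x <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, -1, 0, 2))
  ra <- trial_covariance(x)
  expect_error(fit_cssd(ra, ra, J = 3), "rank",
               class = "cssdelm_config_error")
  expect_silent(fit_cssd(ra, ra, J = 2))
  expect_error(fit_cssd(matrix(c(1, 2, 0, 1), 2, 2), diag(2) / 2, J = 1),
               class = "cssdelm_validation_error")
})

test_that("features satisfy the per-bank normalization contract", {
  withr::local_seed(34)
  bank <- fit_cssd(random_psd_cov(6), random_psd_cov(6), J = 3)
  trial <- matrix(rnorm(6 * 100), 6, 100)
  v <- extract_features(trial, bank)
  expect_length(v, 6L)
  expect_true(all(v <= 0))
  expect_equal(sum(exp(v[1:3])), 1, tolerance = 1e-8)
  expect_equal(sum(exp(v[4:6])), 1, tolerance = 1e-8)

  # J = 1: single-component normalization forces log(1) = 0
  bank1 <- fit_cssd(random_psd_cov(4), random_psd_cov(4), J = 1)
  expect_equal(extract_features(matrix(rnorm(400), 4, 100), bank1), c(0, 0))

  expect_error(extract_features(matrix(rnorm(30), 3, 10), bank),
               class = "cssdelm_validation_error")
})

test_that("features match an independent scalar-loop evaluation", {
  withr::local_seed(35)
  bank <- fit_cssd(random_psd_cov(3), random_psd_cov(3), J = 2)
  for (i in 1:5) {
    trial <- matrix(rnorm(3 * 80), 3, 80)
    expect_equal(extract_features(trial, bank),
                 oracle_features(trial, bank$filters_a, bank$filters_b),
                 tolerance = 1e-12)
  }
})

test_that("features are invariant to invertible spatial mixing", {
  withr::local_seed(36)
  rec <- white_recording(12, n_channels = 5, ns = 300)
  # make the two classes differ so the fit is not fully degenerate
  rec$trials[which(rec$labels == 1L)] <- lapply(
    rec$trials[which(rec$labels == 1L)],
    function(tr) { tr[1, ] <- 2 * tr[1, ]; tr })
  fit_features <- function(r) {
    sp <- split_by_class(r)
    bank <- fit_cssd(class_covariance(sp$class_a),
                     class_covariance(sp$class_b), J = 2)
    as.matrix(featurize_recording(r, bank)[, -(1:2)])
  }
  f0 <- fit_features(rec)
  # trace-ratio-preserving transforms (scaled rotations): exact invariance
  G <- 2.5 * qr.Q(qr(matrix(rnorm(25), 5, 5)))
  mixed <- rec
  mixed$trials <- lapply(rec$trials, function(tr) G %*% tr)
  expect_equal(fit_features(mixed), f0, tolerance = 1e-6)

  # a general invertible mixing perturbs the per-class trace normalization,
  # so invariance is approximate, at the scale of the trace-ratio change
  G2 <- diag(5) + matrix(rnorm(25, sd = 0.3), 5, 5)
  mixed2 <- rec
  mixed2$trials <- lapply(rec$trials, function(tr) G2 %*% tr)
  expect_equal(fit_features(mixed2), f0, tolerance = 0.1)
})

test_that("the top class-A filter recovers a class-specific source direction", {
  hits <- vapply(1:3, function(s) {
    withr::with_seed(400 + s, {
      n <- 4; ns <- 300
      G <- diag(n) + 0.3 * matrix(rnorm(n * n), n, n)
      make <- function(active) {
        replicate(50, {
          z <- matrix(rnorm(n * ns, sd = 0.5), n, ns)
          if (active) z[1, ] <- z[1, ] + rnorm(ns, sd = 2)
          G %*% z
        }, simplify = FALSE)
      }
      bank <- fit_cssd(class_covariance(make(TRUE)),
                       class_covariance(make(FALSE)), J = 1)
      truth <- solve(G)[1, ]
      w <- as.numeric(bank$filters_a[1, ])
      abs(sum(w * truth)) / sqrt(sum(w^2) * sum(truth^2))
    })
  }, numeric(1))
  expect_true(all(hits >= 0.95))
})

test_that("featurize_recording batches per trial and keeps labels", {
  rec <- white_recording(10, n_channels = 22, ns = 120, seed = 37)
  sp <- split_by_class(rec)
  bank <- fit_cssd(class_covariance(sp$class_a),
                   class_covariance(sp$class_b), J = 10)
  fm <- featurize_recording(rec, bank)
  expect_equal(dim(as.matrix(fm[, -(1:2)])), c(10L, 20L))
  expect_equal(fm$label, rec$labels)

  # permuting trials permutes feature rows identically
  perm <- sample(10)
  prec <- rec
  prec$trials <- rec$trials[perm]
  prec$labels <- rec$labels[perm]
  pfm <- featurize_recording(prec, bank)
  expect_equal(as.matrix(pfm[, -(1:2)]),
               as.matrix(fm[perm, -(1:2)]), ignore_attr = TRUE)

  # zero trials give an empty feature matrix of the right width
  empty <- epoched_recording(list(), integer(0), 250,
                             channel_names = rec$channel_names)
  efm <- featurize_recording(empty, bank)
  expect_equal(nrow(efm), 0L)
  expect_equal(ncol(efm), 2L + 20L)
})
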