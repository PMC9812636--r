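test_that("ELM is seed-reproducible and interpolates when overparameterized", {
  feats <- demo_features(n_per_class = 10, d = 3, seed = 5)
  m1 <- train_elm(feats, n_hidden = 40, seed = 9)
  m2 <- train_elm(feats, n_hidden = 40, seed = 9)
  expect_identical(m1$input_weights, m2$input_weights)
  expect_identical(m1$biases, m2$biases)
  expect_equal(m1$output_weights, m2$output_weights, tolerance = 1e-12)
  expect_false(identical(m1$input_weights,
                         train_elm(feats, n_hidden = 40, seed = 10)$input_weights))

  # n_hidden >= N with full-rank H: residual vanishes, training acc 100%
  H <- cssdelm:::hidden_layer(as.matrix(feats[, -(1:2)]),
                              m1$input_weights, m1$biases)
  Tm <- cssdelm:::encode_labels(feats$label)
  expect_lt(sqrt(sum((H %*% m1$output_weights - Tm)^2)), 1e-6)
  expect_equal(accuracy(predict(m1, feats)$label, feats$label), 1)
})

test_that("ELM output weights equal the SVD minimal-norm solution", {
  withr::local_seed(51)
  for (i in 1:100) {
    n <- sample(5:20, 1); d <- sample(2:6, 1); nh <- sample(3:25, 1)
    x <- matrix(rnorm(n * d), n, d)
    labs <- c(1L, 2L, sample(1:2, n - 2, replace = TRUE))
    feats <- as.data.frame(x)
    names(feats) <- sprintf("f%02d", seq_len(d))
    feats$label <- labs
    m <- train_elm(feats, n_hidden = nh, seed = i)
    H <- cssdelm:::hidden_layer(x, m$input_weights, m$biases)
    oracle <- MASS::ginv(H) %*% cssdelm:::encode_labels(labs)
    expect_equal(m$output_weights, oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("kernel ELM solves the closed-form system and matches kernel ridge", {
  # two points, linear kernel, huge C: outputs reproduce targets
  feats <- tibble::tibble(trial = 1:2, label = c(1L, 2L),
                          f01 = c(1, 0), f02 = c(0, 1))
  m <- train_elm_kernel(feats, C = 1e8, kernel = "linear")
  out <- predict(m, feats)
  expect_equal(c(out$score_1, out$score_2), c(1, -1, -1, 1),
               tolerance = 1e-4)
  # residual of (I/C + K) alpha = T
  K <- tcrossprod(as.matrix(feats[, 3:4]))
  resid <- (K + diag(1e-8, 2)) %*% m$alpha - cssdelm:::encode_labels(1:2)
  expect_lt(max(abs(resid)), 1e-8)

  withr::local_seed(52)
  for (i in 1:100) {
    n <- sample(5:25, 1); d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    labs <- c(1L, 2L, sample(1:2, n - 2, replace = TRUE))
    feats <- as.data.frame(x)
    names(feats) <- sprintf("f%02d", seq_len(d))
    feats$label <- labs
    C <- runif(1, 0.5, 50)
    kern <- if (i %% 2 == 0) "rbf" else "linear"
    gamma <- runif(1, 0.1, 2)
    m <- train_elm_kernel(feats, C = C, kernel = kern, gamma = gamma)
    oracle <- oracle_krr(x, cssdelm:::encode_labels(labs), C,
                         gamma = gamma, kernel = kern)
    expect_equal(m$alpha, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("kernel ELM limits behave as the closed form dictates", {
  feats <- demo_features(n_per_class = 8, d = 3, seed = 6)
  x <- as.matrix(feats[, -(1:2)])

  # C -> 0: (I/C + K)^{-1} ~ C I, all outputs shrink to zero
  m_small <- train_elm_kernel(feats, C = 1e-10, gamma = 1)
  expect_lt(max(abs(predict(m_small, feats)$score_1)), 1e-6)

  # gamma -> Inf on distinct points: K -> I, scores -> t * C/(1+C)
  C <- 3
  m_inf <- train_elm_kernel(feats, C = C, gamma = 1e8)
  sc <- predict(m_inf, feats)
  expected <- cssdelm:::encode_labels(feats$label) * C / (1 + C)
  expect_equal(cbind(sc$score_1, sc$score_2), expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("well-separated blobs are classified perfectly, as a centroid oracle", {
  train <- demo_features(n_per_class = 20, d = 2, separation = 6, seed = 7)
  test <- demo_features(n_per_class = 100, d = 2, separation = 6, seed = 8)
  m <- train_elm_kernel(train, C = 10)
  pred <- predict(m, test)$label
  expect_equal(accuracy(pred, test$label), 1)

  # nearest-centroid oracle agrees
  xtr <- as.matrix(train[, -(1:2)]); xte <- as.matrix(test[, -(1:2)])
  mu1 <- colMeans(xtr[train$label == 1, ]); mu2 <- colMeans(xtr[train$label == 2, ])
  d1 <- rowSums(sweep(xte, 2, mu1)^2); d2 <- rowSums(sweep(xte, 2, mu2)^2)
  expect_equal(pred, ifelse(d1 <= d2, 1L, 2L))
})

test_that("kernel training is invariant to training-sample order", {
  feats <- demo_features(n_per_class = 12, d = 3, separation = 2, seed = 9)
  m <- train_elm_kernel(feats, gamma = 0.7)
  perm <- withr::with_seed(10, sample(nrow(feats)))
  m2 <- train_elm_kernel(feats[perm, ], gamma = 0.7)
  probe <- demo_features(n_per_class = 15, d = 3, separation = 2, seed = 11)
  expect_equal(predict(m2, probe)$score_1, predict(m, probe)$score_1,
               tolerance = 1e-10)
})

test_that("kernel ELM accuracy is at least as stable across seeds as basic ELM", {
  train <- demo_features(n_per_class = 15, d = 4, separation = 2.2, seed = 12)
  test <- demo_features(n_per_class = 80, d = 4, separation = 2.2, seed = 13)
  accs <- vapply(1:20, function(s) {
    c(elm = accuracy(predict(train_elm(train, n_hidden = 20, seed = s),
                             test)$label, test$label),
      kern = accuracy(predict(train_elm_kernel(train), test)$label,
                      test$label))
  }, numeric(2))
  expect_lte(sd(accs["kern", ]), sd(accs["elm", ]))
  expect_equal(sd(accs["kern", ]), 0)  # closed form, no randomness
})

test_that("shrinking the training set never helps beyond sampling noise", {
  deltas <- vapply(1:10, function(s) {
    big <- demo_features(n_per_class = 100, d = 4, separation = 2,
                         seed = 100 + s)
    small <- big[c(1:10, 101:110), ]
    test <- demo_features(n_per_class = 100, d = 4, separation = 2,
                          seed = 200 + s)
    accuracy(predict(train_elm_kernel(small), test)$label, test$label) -
      accuracy(predict(train_elm_kernel(big), test)$label, test$label)
  }, numeric(1))
  expect_lte(mean(deltas), 0.02)
})

test_that("input validation catches bad shapes, labels and constants", {
  feats <- demo_features(n_per_class = 5, d = 3, seed = 14)
  expect_error(train_elm(feats, n_hidden = 0), class = "cssdelm_config_error")
  expect_error(train_elm_kernel(feats, C = -1), class = "cssdelm_config_error")
  expect_error(train_elm_kernel(feats, gamma = -2),
               class = "cssdelm_config_error")
  one_class <- feats[feats$label == 1, ]
  expect_error(train_elm_kernel(one_class), class = "cssdelm_validation_error")

  m <- train_elm_kernel(feats)
  expect_error(predict(m, matrix(0, 2, 5)), class = "cssdelm_validation_error")
  me <- train_elm(feats, n_hidden = 10, seed = 1)
  expect_error(predict(me, matrix(0, 2, 5)), class = "cssdelm_validation_error")

  # prediction order equivariance
  probe <- demo_features(n_per_class = 6, d = 3, seed = 15)
  p <- predict(m, probe)
  perm <- c(3, 1, 2, 8, 4:7, 9:12)
  expect_equal(predict(m, probe[perm, ])$score_1, p$score_1[perm])
})

test_that("accuracy counts agreements", {
  expect_equal(accuracy(c(1, 2, 1), c(1, 2, 1)), 1)
  expect_equal(accuracy(c(1, 2), c(2, 1)), 0)
  expect_equal(accuracy(c(1, 2, 1, 2), c(1, 2, 1, 1)), 0.75)
  expect_error(accuracy(integer(0), integer(0)),
               class = "cssdelm_validation_error")
  expect_error(accuracy(1:3, 1:2), class = "cssdelm_validation_error")
})
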