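test_that("partition_features splits evenly with remainder up front", {
  p3 <- partition_features(6, 3, seed = 1)
  expect_equal(lengths(p3, use.names = FALSE), c(2L, 2L, 2L))
  expect_setequal(unlist(p3), 1:6)

  p7 <- partition_features(7, 3, seed = 1)
  expect_equal(lengths(p7, use.names = FALSE), c(3L, 2L, 2L))

  p5 <- partition_features(5, 5, seed = 1)
  expect_equal(lengths(p5, use.names = FALSE), rep(1L, 5))

  expect_error(partition_features(4, 5), "exceeds")
})

test_that("partitions are disjoint and exhaustive for random (n, K)", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(2:200, 1)
    K <- sample(seq_len(n), 1)
    part <- partition_features(n, K)
    flat <- unlist(part)
    expect_equal(sort(flat), seq_len(n))   # exhaustive, no duplicates
    expect_length(part, K)
  }
})

test_that("fit_rotation returns orthonormal loadings with identity fallback", {
  set.seed(67)
  x <- matrix(rnorm(30 * 8), 30, 8)
  C <- fit_rotation(x, subset_cols = 1:4, seed = 5)
  expect_equal(crossprod(C), diag(ncol(C)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # univariate subset: a single unit loading
  C1 <- fit_rotation(x, subset_cols = 3, seed = 5)
  expect_equal(abs(as.numeric(C1)), 1)

  # constant subset triggers the identity fallback
  xc <- cbind(x, 7)
  expect_message(Cc <- fit_rotation(xc, subset_cols = 9, seed = 5),
                 "identity fallback")
  expect_equal(Cc, diag(1))
})

test_that("build_rotation_matrix places blocks on original feature rows", {
  # identity blocks: rotation acts as a column permutation of X
  part <- list(c(3L, 1L), c(2L, 4L))
  coefs <- list(diag(2), diag(2))
  R <- build_rotation_matrix(part, coefs, 4)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(x %*% R, x[, c(3, 1, 2, 4)])
  # every row's nonzeros are confined to one block
  expect_true(all(rowSums(R != 0) == 1))

  # single subset covering all features: R equals the loading matrix
  xb <- matrix(rnorm(60), 15, 4)
  C <- prcomp(xb)$rotation
  expect_equal(build_rotation_matrix(list(1:4), list(C), 4), unname(C),
               ignore_attr = TRUE)

  expect_error(build_rotation_matrix(part, list(diag(2), diag(3)), 4),
               "match subset sizes")
})

test_that("K = 1, L = 1 with full-rank PCA reduces to the base SVM", {
  # a full PCA rotation is orthogonal, so the RBF kernel matrix -- and
  # hence the SVM and its Platt calibration -- is unchanged
  set.seed(71)
  n <- 40; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  y <- as.integer(x[, 1] + 0.5 * rnorm(n) > 0)
  gam <- 1 / (p * mean(apply(x, 2, var)))
  params <- list(kernel = "radial", cost = 1, gamma = gam)
  model <- rotation_forest(x, y, K = 1, L = 1, bootstrap_fraction = 1,
                           svm_params = params, seed = 31)
  expect_equal(crossprod(model$members[[1]]$rotation), diag(p),
               tolerance = 1e-10)  # orthogonal: all components retained
  xt <- matrix(rnorm(20 * p), 20, p)
  mu <- predict_scores(model, xt)

  base <- carbonylr:::fit_svm_prob(x, y, params)
  expect_equal(unname(mu[, "mu_pos"]),
               unname(carbonylr:::predict_svm_prob(base, xt)),
               tolerance = 1e-6)
})

test_that("credibilities average subclassifier probabilities and sum to 1", {
  fb <- generate_feature_blobs(30, dim = 12, separation = 3, seed = 3)
  model <- rotation_forest(fb$x, fb$labels, K = 4, L = 3, seed = 7)
  mu <- predict_scores(model, fb$x)
  expect_equal(unname(mu[, "mu_pos"] + mu[, "mu_neg"]), rep(1, 60))
  per_member <- sapply(model$members, function(m) {
    carbonylr:::predict_svm_prob(m$classifier, fb$x %*% m$rotation)
  })
  expect_equal(unname(mu[, "mu_pos"]), unname(rowMeans(per_member)))
})

test_that("rotation consistency: stored matrices reproduce training scores", {
  fb <- generate_feature_blobs(25, dim = 10, separation = 4, seed = 13)
  model <- rotation_forest(fb$x, fb$labels, K = 3, L = 4, seed = 17)
  s1 <- predict_scores(model, fb$x)
  s2 <- predict_scores(model, fb$x)
  expect_identical(s1, s2)
})

test_that("fitting is deterministic under a fixed seed", {
  fb <- generate_feature_blobs(25, dim = 10, separation = 2, seed = 19)
  m1 <- rotation_forest(fb$x, fb$labels, K = 3, L = 2, seed = 23)
  m2 <- rotation_forest(fb$x, fb$labels, K = 3, L = 2, seed = 23)
  xt <- matrix(rnorm(40), 4, 10)
  expect_identical(predict_scores(m1, xt), predict_scores(m2, xt))
})

test_that("separable blobs are fit to high training accuracy", {
  fb <- generate_feature_blobs(30, dim = 20, separation = 6, seed = 29)
  model <- rotation_forest(fb$x, fb$labels, K = 4, L = 2, seed = 31)
  calls <- predict_labels(model, fb$x)
  expect_equal(mean(calls == fb$labels), 1)
})

test_that("prediction guards dimensions and threshold bounds", {
  fb <- generate_feature_blobs(15, dim = 8, separation = 5, seed = 37)
  model <- rotation_forest(fb$x, fb$labels, K = 2, L = 1, seed = 41)
  expect_error(predict_scores(model, matrix(0, 2, 9)), "dimension mismatch")
  expect_error(predict_labels(model, fb$x, threshold = 0), "threshold")
  expect_error(rotation_forest(fb$x, rep(1L, 30), K = 2), "both classes")

  # boundary credibility goes to the positive class
  expect_equal(predict_labels(model, fb$x)[1],
               as.integer(predict_scores(model, fb$x)[1, "mu_pos"] >= 0.5))
})

test_that("models survive a save/load round trip", {
  fb <- generate_feature_blobs(15, dim = 8, separation = 5, seed = 43)
  model <- rotation_forest(fb$x, fb$labels, K = 2, L = 1, seed = 47)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict_scores(back, fb$x), predict_scores(model, fb$x))

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a carbonylr model")
})
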