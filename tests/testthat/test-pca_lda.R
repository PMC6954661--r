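test_that("fit_pca: variance ratios, reconstruction, orthogonality, signs", {
  # points on a line in 2-D: one component explains everything
  t <- seq(-2, 2, length.out = 10)
  X <- cbind(3 * t, -4 * t)
  pm <- fit_pca(X, 1)
  expect_equal(pm$explained_variance_ratio, 1.0, tolerance = 1e-12)

  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  k <- 6  # full rank: reconstruction must be exact
  pm <- fit_pca(X, k)
  rec <- pm$scores %*% t(pm$loadings) +
    matrix(pm$mean_spectrum, 20, 6, byrow = TRUE)
  expect_equal(rec, X, tolerance = 1e-8)
  expect_equal(crossprod(pm$loadings), diag(k), tolerance = 1e-8)
  # scores mutually orthogonal; cross-check against an independent eigen route
  G <- crossprod(pm$scores)
  expect_equal(G - diag(diag(G)), matrix(0, k, k), tolerance = 1e-8)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(pm$explained_variance_ratio, (ev / sum(ev))[1:k],
               tolerance = 1e-8)
  # sign convention: largest |entry| of each loading column positive
  for (j in seq_len(k))
    expect_gt(pm$loadings[which.max(abs(pm$loadings[, j])), j], 0)
  expect_error(fit_pca(X, 25), "k must be")
})

test_that("pca_project reproduces training scores and zeroes the mean", {
  set.seed(6)
  X <- matrix(rnorm(15 * 8), 15, 8)
  pm <- fit_pca(X, 3)
  expect_equal(pca_project(pm, X), pm$scores, tolerance = 1e-10)
  expect_equal(as.numeric(pca_project(pm, pm$mean_spectrum)), rep(0, 3),
               tolerance = 1e-10)
  # mean + loading column j projects to the unit vector e_j
  expect_equal(as.numeric(pca_project(pm, pm$mean_spectrum + pm$loadings[, 2])),
               c(0, 1, 0), tolerance = 1e-8)
  expect_error(pca_project(pm, matrix(0, 2, 5)), "mismatch")
})

test_that("fit_lda pooled covariance matches the hand formula", {
  # two 1-D classes {0,0,2,2} and {10,10,12,12}: means 1 and 11; each class
  # scatter = 4, pooled = (4 + 4) / (8 - 2) = 4/3
  sc <- matrix(c(0, 0, 2, 2, 10, 10, 12, 12), ncol = 1)
  lab <- rep(c("a", "b"), each = 4)
  lm <- fit_lda(sc, lab)
  expect_equal(as.numeric(lm$class_means), c(1, 11))
  expect_equal(as.numeric(lm$pooled_cov), 8 / 6)
  expect_equal(as.numeric(fit_lda(sc, lab, denominator = "n")$pooled_cov),
               8 / 8)
  # classes with identical covariance by construction: pooling reproduces it
  set.seed(3)
  Z <- matrix(rnorm(12 * 2), 12, 2)
  Zc <- sweep(Z, 2, colMeans(Z))
  sc2 <- rbind(Zc, sweep(Zc, 2, c(5, 5), `+`))
  lab2 <- rep(c("a", "b"), each = 12)
  lm2 <- fit_lda(sc2, lab2, denominator = "n")
  expect_equal(lm2$pooled_cov, crossprod(Zc) / 12, tolerance = 1e-8)
  expect_error(fit_lda(matrix(1:3, 3), c("a", "a", "b")), ">= 2 samples")
  expect_error(fit_lda(matrix(rnorm(8), 4, 2), rep(c("a", "b"), 2)),
               "fewer PCs|dimension")
})

test_that("lda_score evaluates the Mahalanobis quadratic form", {
  lm <- structure(list(class_means = matrix(c(0, 0), 1, 2,
                                            dimnames = list("a", NULL)),
                       pooled_cov = diag(c(1, 4)),
                       chol = chol(diag(c(1, 4))),
                       class_order = "a"),
                  class = "lda_model")
  # C = diag(1,4), x - mean = (2,2): L = 4/1 + 4/4 = 5
  expect_equal(as.numeric(lda_score(lm, c(2, 2))), 5)
  # zero at the class mean
  expect_equal(as.numeric(lda_score(lm, c(0, 0))), 0)
  # identity covariance reduces to squared Euclidean distance
  lmI <- structure(list(class_means = matrix(c(1, 2), 1, 2,
                                             dimnames = list("a", NULL)),
                        pooled_cov = diag(2), chol = chol(diag(2)),
                        class_order = "a"),
                   class = "lda_model")
  x <- c(4, 6)
  expect_equal(as.numeric(lda_score(lmI, x)), sum((x - c(1, 2))^2))
})

test_that("lda_score is invariant under invertible reparameterization", {
  set.seed(8)
  sc <- rbind(matrix(rnorm(20 * 3), 20, 3),
              matrix(rnorm(20 * 3, mean = 2), 20, 3))
  lab <- rep(c("a", "b"), each = 20)
  A <- matrix(c(2, 1, 0, -1, 3, 0.5, 0, 1, 1), 3, 3)
  x <- matrix(rnorm(5 * 3), 5, 3)
  L1 <- lda_score(fit_lda(sc, lab), x)
  L2 <- lda_score(fit_lda(sc %*% t(A), lab), x %*% t(A))
  expect_equal(L1, L2, tolerance = 1e-8)
})

test_that("lda_classify: argmin rule, ties, nearest-centroid equivalence", {
  sc <- matrix(c(0, 0, 2, 2, 10, 10, 12, 12), ncol = 1)
  lab <- rep(c("a", "b"), each = 4)
  lm <- fit_lda(sc, lab)
  # class means classify to their own classes
  expect_equal(as.character(lda_classify(lm, lm$class_means)), c("a", "b"))
  # midpoint: tie -> first class in class_order
  expect_equal(as.character(lda_classify(lm, matrix(6))), "a")

  # with spherical pooled covariance, decisions equal nearest-centroid
  set.seed(10)
  for (rep in 1:20) {
    scr <- rbind(matrix(rnorm(10 * 2), 10, 2),
                 matrix(rnorm(10 * 2, 3), 10, 2))
    labr <- rep(c("a", "b"), each = 10)
    lmr <- fit_lda(scr, labr)
    lmr$pooled_cov <- diag(2) * 0.7
    lmr$chol <- chol(lmr$pooled_cov)
    Xq <- matrix(rnorm(12 * 2), 12, 2)
    got <- as.character(lda_classify(lmr, Xq))
    want <- apply(Xq, 1, function(x) {
      d <- apply(lmr$class_means, 1, function(mk) sum((x - mk)^2))
      c("a", "b")[which.min(d)]
    })
    expect_equal(got, want)
  }
})

test_that("venetian blinds: modulo folds, conservation, oracle equivalence", {
  ds <- make_fixture(10, 8, separation = 3, seed = 13)  # 20 samples
  X <- ds$intensities
  cv <- venetian_blinds_cv(X, ds$labels, max_pcs = 4, n_splits = 10)
  # every sample predicted exactly once per k (no NA anywhere)
  expect_false(anyNA(cv$predictions[, cv$n_pcs_grid]))
  expect_true(all(cv$cv_error >= 0 & cv$cv_error <= 1))
  # independent naive reimplementation agrees exactly
  expect_equal(cv$cv_error, oracle_cv_error(X, ds$labels, 4, 10),
               tolerance = 1e-12)
  expect_error(venetian_blinds_cv(X, ds$labels, 4, n_splits = 50),
               "n_splits")
})

test_that("perfectly separated classes give zero CV error at k = 1", {
  ds <- make_fixture(10, 5, separation = 30, seed = 14)
  cv <- venetian_blinds_cv(ds$intensities, ds$labels, max_pcs = 3)
  expect_equal(cv$cv_error[1], 0)
})

test_that("select_n_pcs takes the smallest argmin", {
  mk <- function(err) structure(list(n_pcs_grid = seq_along(err),
                                     cv_error = err, n_splits = 10L),
                                class = "cv_curve")
  expect_equal(select_n_pcs(mk(c(0.3, 0.1, 0.1, 0.2))), 2L)
  expect_equal(select_n_pcs(mk(c(0.5, 0.4, 0.3))), 3L)   # monotone decreasing
  expect_equal(select_n_pcs(mk(rep(0.2, 4))), 1L)        # constant
})

test_that("fit_pca_lda: end-to-end on separable blobs, prediction works", {
  ds <- make_fixture(15, 10, separation = 12, seed = 15)
  model <- fit_pca_lda(ds, max_pcs = 5)
  expect_s3_class(model, "pca_lda_model")
  expect_equal(model$training_accuracy, 100)
  expect_lte(model$n_pcs, 5)
  expect_equal(model$cv_accuracy,
               100 * (1 - model$cv$cv_error[match(model$n_pcs,
                                                  model$cv$n_pcs_grid)]))
  # predicting the training data reproduces the labels
  expect_equal(as.character(predict(model, ds)), as.character(ds$labels))
  sc <- predict(model, ds, type = "score")
  expect_true(all(sc >= 0))
  expect_error(fit_pca_lda(subset_samples(ds, 1:15), max_pcs = 3),
               "2 classes")
})

test_that("classification is permutation-equivariant in samples", {
  ds <- make_fixture(12, 6, separation = 4, seed = 16)
  model <- fit_pca_lda(ds, max_pcs = 3)
  X <- ds$intensities
  perm <- sample(nrow(X))
  expect_equal(as.character(predict(model, X[perm, ])),
               as.character(predict(model, X))[perm])
})

test_that("model JSON serialization preserves predictions exactly", {
  ds <- make_fixture(12, 8, separation = 3, seed = 21)
  model <- fit_pca_lda(ds, max_pcs = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  Xq <- make_fixture(6, 8, separation = 3, seed = 22)$intensities
  expect_equal(predict(back, Xq, type = "score"),
               predict(model, Xq, type = "score"), tolerance = 1e-12)
  expect_identical(as.character(predict(back, Xq)),
                   as.character(predict(model, Xq)))
  expect_equal(back$n_pcs, model$n_pcs)
  expect_equal(back$cv$cv_error, model$cv$cv_error)
})
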