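# PCA-LDA: principal-component scores feed a pooled-covariance Mahalanobis
# linear discriminant (non-Bayesian: no priors, no log-determinant term).
# The number of PCs is chosen by venetian-blinds cross-validation (interleaved
# folds, sample i -> fold i mod n_splits) at the minimum misclassification
# error, smallest k winning ties.

#' Fit a PCA model
#'
#' Centers `X` on its column means and extracts the top-`k` right singular
#' directions. Column signs are fixed so the largest-magnitude loading
#' element in each column is positive, making the decomposition fully
#' deterministic.
#'
#' @param X Numeric matrix, samples x variables.
#' @param k Number of components, `k <= min(n_samples - 1, n_variables)`.
#' @return An object of class `pca_model`: `mean_spectrum`, `loadings`
#'   (variables x k, orthonormal), `explained_variance_ratio` (length k),
#'   `scores` (training scores, samples x k).
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > kmax)
    stop(sprintf("k must be in 1..%d (min(n_samples - 1, n_variables))", kmax))
  k <- as.integer(k)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = k)
  V <- sv$v
  # deterministic sign: largest |loading| entry positive per column
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  d2 <- sv$d^2
  structure(list(mean_spectrum = mu,
                 loadings = V,
                 explained_variance_ratio = (d2 / sum(d2))[seq_len(k)],
                 scores = Xc %*% V),
            class = "pca_model")
}

#' Project spectra onto a fitted PCA model
#'
#' @param m A `pca_model`.
#' @param X Numeric matrix with the same number of variables as the training
#'   data (a single spectrum may be given as a vector).
#' @return Score matrix `(X - mean) %*% loadings`.
#' @export
pca_project <- function(m, X) {
  stopifnot(inherits(m, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(m$mean_spectrum))
    stop("variable count mismatch: model has ", length(m$mean_spectrum),
         ", data has ", ncol(X))
  sweep(as.matrix(X), 2L, m$mean_spectrum) %*% m$loadings
}

#' Fit the pooled-covariance linear discriminant
#'
#' Computes per-class mean score vectors and the pooled within-class
#' covariance `C_pooled = sum_k sum_{i in k} (x_i - xbar_k)(x_i - xbar_k)^T / d`
#' with denominator `d = N - K` (unbiased pooled estimator, default) or
#' `d = N`.
#'
#' @param scores Numeric matrix, samples x score dimensions.
#' @param labels Factor (or vector) of class labels, >= 2 classes with >= 2
#'   samples each.
#' @param denominator `"n_minus_k"` (default) or `"n"`.
#' @return An object of class `lda_model`: `class_means` (K x d matrix),
#'   `pooled_cov`, its Cholesky factor, and `class_order`.
#' @export
fit_lda <- function(scores, labels, denominator = c("n_minus_k", "n")) {
  denominator <- match.arg(denominator)
  scores <- as.matrix(scores)
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  if (length(labels) != nrow(scores))
    stop("labels length must match nrow(scores)")
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("every class needs >= 2 samples; offending: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  N <- nrow(scores); d <- ncol(scores)
  if (d >= N - K)
    stop("score dimension must be < n_samples - n_classes; use fewer PCs")
  means <- matrix(0, K, d, dimnames = list(levels(labels), NULL))
  S <- matrix(0, d, d)
  for (k in seq_len(K)) {
    Xi <- scores[labels == levels(labels)[k], , drop = FALSE]
    means[k, ] <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, means[k, ])
    S <- S + crossprod(Xc)
  }
  den <- if (denominator == "n_minus_k") N - K else N
  C <- S / den
  R <- tryCatch(chol(C), error = function(e)
    stop("pooled covariance is singular; use fewer PCs"))
  if (rcond(R) < 1e-6)  # rcond of the factor ~ sqrt of the matrix's; 1e-12 on C
    stop("pooled covariance is numerically singular (condition number > 1e12); use fewer PCs")
  structure(list(class_means = means, pooled_cov = C, chol = R,
                 class_order = levels(labels), denominator = denominator),
            class = "lda_model")
}

#' Mahalanobis discriminant scores
#'
#' For each sample `x` and class `k`, computes
#' `L_ik = (x - xbar_k)^T C_pooled^-1 (x - xbar_k)`; smaller is closer.
#'
#' @param m An `lda_model`.
#' @param X Score matrix (or a single score vector).
#' @return Matrix n x K of non-negative scores, columns in `class_order`.
#' @export
lda_score <- function(m, X) {
  stopifnot(inherits(m, "lda_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ncol(m$class_means)) stop("score dimension mismatch")
  K <- nrow(m$class_means)
  L <- matrix(0, nrow(X), K, dimnames = list(NULL, m$class_order))
  for (k in seq_len(K)) {
    Dk <- sweep(X, 2L, m$class_means[k, ])
    Z <- backsolve(m$chol, t(Dk), transpose = TRUE)  # R^T z = d
    L[, k] <- colSums(Z^2)
  }
  L
}

#' Classify score vectors with a fitted discriminant
#'
#' Assigns each sample to the class minimising [lda_score()]; ties go to the
#' first class in `class_order`.
#'
#' @inheritParams lda_score
#' @return Factor of predicted classes with levels `class_order`.
#' @export
lda_classify <- function(m, X) {
  L <- lda_score(m, X)
  factor(m$class_order[max.col(-L, ties.method = "first")],
         levels = m$class_order)
}

#' Venetian-blinds cross-validation over the number of PCs
#'
#' Assigns sample `i` (current row order) to fold `((i - 1) mod n_splits) + 1`.
#' For each candidate `k` in `1..max_pcs`, PCA and LDA are refit on each
#' fold's complement (no information leakage) and the held-out fold is
#' predicted; the pooled misclassification fraction over all held-out
#' predictions is the CV error at `k`. Internally the fold PCA is computed
#' once at `max_pcs` and truncated to its first `k` columns, which yields
#' results identical to refitting at each `k` because SVD components are
#' nested and deterministically ordered.
#'
#' @param X Numeric matrix, samples x variables (training set, in the row
#'   order produced by the splitter).
#' @param labels Class labels, length `nrow(X)`.
#' @param max_pcs Largest number of PCs to consider.
#' @param n_splits Number of interleaved folds (default 10).
#' @return An object of class `cv_curve`: `n_pcs_grid`, `cv_error`,
#'   `n_splits`.
#' @export
venetian_blinds_cv <- function(X, labels, max_pcs, n_splits = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  if (n_splits > n) stop("n_splits cannot exceed the number of samples")
  if (max_pcs < 1L) stop("max_pcs must be >= 1")
  max_pcs <- as.integer(min(max_pcs, ncol(X), n - 2L))
  folds <- ((seq_len(n) - 1L) %% n_splits) + 1L
  pred <- matrix(NA_integer_, n, max_pcs)
  for (f in seq_len(n_splits)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (min(table(labels[tr])) < 2L) {
      warning("fold ", f, " skipped: a class has < 2 training samples")
      next
    }
    kf <- min(max_pcs, length(tr) - 1L, ncol(X),
              length(tr) - nlevels(labels) - 1L)
    if (kf < 1L) {
      warning("fold ", f, " skipped: not enough samples for any PCs")
      next
    }
    pm <- fit_pca(X[tr, , drop = FALSE], kf)
    ste <- pca_project(pm, X[te, , drop = FALSE])
    for (k in seq_len(kf)) {
      lm <- tryCatch(fit_lda(pm$scores[, seq_len(k), drop = FALSE], labels[tr]),
                     error = function(e) NULL)
      if (is.null(lm)) next
      pred[te, k] <- as.integer(factor(
        as.character(lda_classify(lm, ste[, seq_len(k), drop = FALSE])),
        levels = levels(labels)))
    }
  }
  err <- vapply(seq_len(max_pcs), function(k) {
    ok <- !is.na(pred[, k])
    if (!any(ok)) return(NA_real_)
    mean(pred[ok, k] != as.integer(labels)[ok])
  }, numeric(1))
  keep <- !is.na(err)
  structure(list(n_pcs_grid = seq_len(max_pcs)[keep], cv_error = err[keep],
                 n_splits = as.integer(n_splits), predictions = pred),
            class = "cv_curve")
}

#' Choose the number of PCs from a CV curve
#'
#' Returns the smallest `k` attaining the minimum cross-validation error.
#'
#' @param curve A `cv_curve`.
#' @return Integer number of PCs.
#' @export
select_n_pcs <- function(curve) {
  stopifnot(inherits(curve, "cv_curve"), length(curve$cv_error) > 0)
  curve$n_pcs_grid[which.min(curve$cv_error)]
}

#' Fit the full PCA-LDA classification pipeline
#'
#' Runs [venetian_blinds_cv()] on the training data, picks the number of PCs
#' with [select_n_pcs()], then refits PCA and LDA on the complete training
#' set at the chosen dimensionality. Training accuracy and cross-validation
#' accuracy (1 - CV error at the chosen k) are recorded.
#'
#' @param train A [spectral_dataset] (the training set; row order is the
#'   splitter's order and drives the venetian-blinds fold assignment), or a
#'   numeric matrix if `labels` is supplied.
#' @param max_pcs Largest number of PCs considered (default 20).
#' @param n_splits Venetian-blinds folds (default 10).
#' @param labels Required when `train` is a bare matrix.
#' @return An object of class `pca_lda_model`: `pca`, `lda`, `n_pcs`,
#'   `cv` (the `cv_curve`), `training_accuracy` and `cv_accuracy` (percent),
#'   `cumulative_explained_variance` at the chosen k.
#' @export
fit_pca_lda <- function(train, max_pcs = 20L, n_splits = 10L, labels = NULL) {
  if (inherits(train, "spectral_dataset")) {
    X <- train$intensities
    labels <- train$labels
  } else {
    X <- as.matrix(train)
    if (is.null(labels)) stop("labels required when train is a matrix")
  }
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  if (nlevels(labels) < 2L) stop("classification needs at least 2 classes")
  curve <- venetian_blinds_cv(X, labels, max_pcs, n_splits)
  k <- select_n_pcs(curve)
  pca <- fit_pca(X, k)
  lda <- fit_lda(pca$scores, labels)
  pred_tr <- lda_classify(lda, pca$scores)
  structure(list(pca = pca, lda = lda, n_pcs = k, cv = curve,
                 training_accuracy = 100 * mean(pred_tr == labels),
                 cv_accuracy = 100 * (1 - curve$cv_error[match(k, curve$n_pcs_grid)]),
                 cumulative_explained_variance =
                   100 * sum(pca$explained_variance_ratio),
                 class_order = lda$class_order),
            class = "pca_lda_model")
}

#' @export
print.pca_lda_model <- function(x, ...) {
  cat(sprintf("<pca_lda_model> %d PCs (%.1f%% cumulative explained variance)\n",
              x$n_pcs, x$cumulative_explained_variance))
  cat(sprintf("  training accuracy %.1f%%, CV accuracy %.1f%% (%d-fold venetian blinds)\n",
              x$training_accuracy, x$cv_accuracy, x$cv$n_splits))
  invisible(x)
}

#' Predict classes for new spectra
#'
#' @param object A `pca_lda_model`.
#' @param newdata A [spectral_dataset] or an intensity matrix with the
#'   training variable count.
#' @param type `"class"` (default) for predicted labels, `"score"` for the
#'   per-class Mahalanobis scores.
#' @param ... Unused.
#' @return Factor of predicted classes, or a score matrix.
#' @export
predict.pca_lda_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectral_dataset")) newdata$intensities
       else as.matrix(newdata)
  sc <- pca_project(object$pca, X)
  if (type == "score") lda_score(object$lda, sc) else lda_classify(object$lda, sc)
}

#' Serialize / deserialize a fitted PCA-LDA model as JSON
#'
#' Matrices are stored as row-major nested lists, human-inspectable with any
#' JSON tool; `read_model()` reconstructs a model whose predictions are
#' identical to the original's.
#'
#' @param model A `pca_lda_model`.
#' @param path Output (or input) JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pca_lda_model"))
  jsonlite::write_json(
    list(n_pcs = model$n_pcs,
         class_order = model$class_order,
         pca = list(mean_spectrum = model$pca$mean_spectrum,
                    loadings = model$pca$loadings,
                    explained_variance_ratio = model$pca$explained_variance_ratio),
         lda = list(class_means = model$lda$class_means,
                    pooled_cov = model$lda$pooled_cov,
                    denominator = model$lda$denominator),
         cv = list(n_pcs_grid = model$cv$n_pcs_grid,
                   cv_error = model$cv$cv_error,
                   n_splits = model$cv$n_splits),
         training_accuracy = model$training_accuracy,
         cv_accuracy = model$cv_accuracy,
         cumulative_explained_variance = model$cumulative_explained_variance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- as.matrix(x$lda$pooled_cov)
  pca <- structure(list(mean_spectrum = x$pca$mean_spectrum,
                        loadings = as.matrix(x$pca$loadings),
                        explained_variance_ratio =
                          x$pca$explained_variance_ratio,
                        scores = NULL),
                   class = "pca_model")
  lda <- structure(list(class_means = matrix(as.matrix(x$lda$class_means),
                                             nrow = length(x$class_order),
                                             dimnames = list(x$class_order, NULL)),
                        pooled_cov = C, chol = chol(C),
                        class_order = x$class_order,
                        denominator = x$lda$denominator),
                   class = "lda_model")
  structure(list(pca = pca, lda = lda, n_pcs = x$n_pcs,
                 cv = structure(list(n_pcs_grid = x$cv$n_pcs_grid,
                                     cv_error = x$cv$cv_error,
                                     n_splits = x$cv$n_splits),
                                class = "cv_curve"),
                 training_accuracy = x$training_accuracy,
                 cv_accuracy = x$cv_accuracy,
                 cumulative_explained_variance =
                   x$cumulative_explained_variance,
                 class_order = x$class_order),
            class = "pca_lda_model")
}
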