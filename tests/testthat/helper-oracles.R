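# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and dense linear algebra only.

# Exhaustive max-min Kennard-Stone selector: all-pairs seeding, then for each
# step an explicit scan of every remaining candidate's minimum distance to
# the selected set. Ties broken by lowest index. Returns selection order.
oracle_ks <- function(X, n_sel) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bestd <- -1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- d(i, j)
    if (dij > bestd) { bestd <- dij; best <- c(i, j) }
  }
  if (n_sel == 1L) return(best[1])
  sel <- best
  while (length(sel) < n_sel) {
    cand_best <- NA_integer_; cand_val <- -1
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) mind <- min(mind, d(i, s))
      if (mind > cand_val) { cand_val <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Naive venetian-blinds CV: explicit re-implementation with no shared state;
# PCA and LDA are refit from scratch at every (fold, k) using base tools.
oracle_cv_error <- function(X, labels, max_pcs, n_splits = 10L) {
  n <- nrow(X)
  labels <- factor(labels, levels = unique(as.character(labels)))
  folds <- ((seq_len(n) - 1L) %% n_splits) + 1L
  err <- numeric(max_pcs)
  for (k in seq_len(max_pcs)) {
    wrong <- 0L; total <- 0L
    for (f in seq_len(n_splits)) {
      tr <- which(folds != f); te <- which(folds == f)
      mu <- colMeans(X[tr, , drop = FALSE])
      Xc <- sweep(X[tr, , drop = FALSE], 2, mu)
      V <- svd(Xc)$v[, seq_len(k), drop = FALSE]
      Str <- Xc %*% V
      Ste <- sweep(X[te, , drop = FALSE], 2, mu) %*% V
      lev <- levels(labels)
      means <- matrix(0, length(lev), k)
      for (li in seq_along(lev))
        means[li, ] <- colMeans(Str[labels[tr] == lev[li], , drop = FALSE])
      S <- matrix(0, k, k)
      for (l in lev) {
        Z <- sweep(Str[labels[tr] == l, , drop = FALSE], 2,
                   colMeans(Str[labels[tr] == l, , drop = FALSE]))
        S <- S + t(Z) %*% Z
      }
      C <- S / (length(tr) - length(lev))
      Ci <- solve(C)
      for (i in seq_along(te)) {
        L <- apply(means, 1, function(mk) {
          dv <- Ste[i, ] - mk
          as.numeric(t(dv) %*% Ci %*% dv)
        })
        pred <- lev[which.min(L)]
        total <- total + 1L
        if (pred != as.character(labels[te[i]])) wrong <- wrong + 1L
      }
    }
    err[k] <- wrong / total
  }
  err
}

# Lower-convex-hull baseline by the all-pairs supporting-line test: a line
# through points (i, j) supports the hull iff no point lies below it; the
# baseline is the pointwise maximum over supporting lines.
oracle_rubberband_baseline <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- (y[j] - y[i]) / (x[j] - x[i])
    b <- y[i] - a * x[i]
    line <- a * x + b
    if (all(y >= line - 1e-9)) base <- pmax(base, line)
  }
  base
}

# Dense direct solve of the asymmetric penalized least-squares system, same
# weight iteration but dense base-R linear algebra.
oracle_awls <- function(y, lambda, p, max_iter) {
  n <- length(y)
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  P <- lambda * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  z
}

# published Savitzky-Golay smoothing coefficients, window 7, quadratic
SG7_QUADRATIC <- c(-2, 3, 6, 7, 6, 3, -2) / 21

# small helper: dataset from a plain matrix
ds_from_matrix <- function(X, labels = rep("a", nrow(X)), wn = seq_len(ncol(X))) {
  spectral_dataset(X, wn, labels)
}
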