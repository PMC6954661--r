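# Spectral preprocessing: biofingerprint excision, Savitzky-Golay smoothing,
# rubberband (lower convex hull) and asymmetric-least-squares baseline
# correction, peak (Amide I) and vector normalization. Every step preserves
# the sample count and order; only cut_region changes the variable count.

#' Excise a wavenumber region
#'
#' Keeps exactly the variables with `lo <= wavenumber <= hi` (inclusive),
#' preserving the axis order. The conventional biofingerprint region is
#' 900-1800 cm^-1.
#'
#' @param ds A [spectral_dataset].
#' @param lo,hi Region bounds in cm^-1, `lo < hi`.
#' @return A [spectral_dataset] restricted to the region.
#' @export
cut_region <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectral_dataset"), lo < hi)
  keep <- which(ds$wavenumbers >= lo & ds$wavenumbers <= hi)
  if (length(keep) == 0L)
    stop(sprintf("range error: [%g, %g] contains no axis points", lo, hi))
  out <- ds
  out$intensities <- ds$intensities[, keep, drop = FALSE]
  out$wavenumbers <- ds$wavenumbers[keep]
  out
}

# Savitzky-Golay projection matrix for one window: H = A (A^T A)^-1 A^T with
# A the Vandermonde matrix of offsets -h..h and powers 0..polyorder.
sg_projection <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing
#'
#' Per-spectrum local polynomial smoothing on an assumed-uniform axis grid
#' (standard practice for evenly sampled FTIR/Raman spectra). Interior points
#' use the central smoothing coefficients; the first and last half-windows
#' are smoothed by evaluating the polynomial fitted to the first/last full
#' window (no shortening of the spectrum).
#'
#' @param ds A [spectral_dataset].
#' @param window Odd window length in points, `window > polyorder` and
#'   `window <= n_variables`.
#' @param polyorder Polynomial order (default 2, the usual chemometrics
#'   choice).
#' @return Smoothed [spectral_dataset], same shape.
#' @export
savgol_smooth <- function(ds, window, polyorder = 2L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("parameter error: window must be odd")
  if (window <= polyorder) stop("parameter error: window must exceed polyorder")
  p <- n_variables(ds)
  if (window > p) stop("parameter error: window exceeds the number of variables")
  H <- sg_projection(window, polyorder)
  h <- (window - 1L) %/% 2L
  X <- ds$intensities
  out <- X
  n <- nrow(X)
  center <- H[h + 1L, ]
  for (i in seq_len(n)) {
    y <- X[i, ]
    s <- stats::filter(y, center, sides = 2)
    s[seq_len(h)] <- H[seq_len(h), ] %*% y[seq_len(window)]
    s[(p - h + 1L):p] <- H[(h + 2L):window, ] %*% y[(p - window + 1L):p]
    out[i, ] <- s
  }
  ds$intensities <- out
  ds
}

# lower convex hull (monotone chain) of points with strictly ascending x;
# returns indices of hull vertices, first and last point always included
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      k <- hull[m - 1L]; j <- hull[m]
      # remove j if it lies on or above the segment k -> i
      if ((x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k]) <= 0)
        m <- m - 1L
      else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

#' Rubberband baseline correction
#'
#' Subtracts, per spectrum, the lower convex hull of the points
#' `(wavenumber, intensity)`. Hull contact points map to exactly zero and the
#' corrected spectrum is non-negative at (and between) hull vertices only up
#' to the convexity of the signal; spectrum endpoints always become zero.
#'
#' @param ds A [spectral_dataset] with at least 3 variables.
#' @return Baseline-corrected [spectral_dataset].
#' @export
rubberband_baseline <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  p <- n_variables(ds)
  if (p < 3L) stop("rubberband needs at least 3 variables")
  wn <- ds$wavenumbers
  desc <- wn[1] > wn[p]
  ord <- if (desc) rev(seq_len(p)) else seq_len(p)
  x <- wn[ord]
  X <- ds$intensities
  out <- X
  for (i in seq_len(nrow(X))) {
    y <- X[i, ord]
    h <- lower_hull_idx(x, y)
    base <- stats::approx(x[h], y[h], xout = x, rule = 2)$y
    out[i, ord] <- y - base
  }
  ds$intensities <- out
  ds
}

# one-spectrum asymmetric least squares (Whittaker smoother, 2nd differences)
asls_vec <- function(y, lambda, p, max_iter, DtD) {
  n <- length(y)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  z
}

#' Asymmetric weighted least squares (AWLS) baseline correction
#'
#' Estimates each spectrum's baseline with a Whittaker smoother under
#' asymmetric weights (points above the current baseline get weight
#' `asymmetry`, points below get `1 - asymmetry`) and subtracts it. This is
#' the standard asymmetric-least-squares construction used here as the
#' stand-in for proprietary "automatic weighted least squares" toolbox
#' baselines, whose exact algorithm is unpublished.
#'
#' Iteration stops when the largest weight change falls below 1e-6 or after
#' `max_iter` rounds.
#'
#' @param ds A [spectral_dataset].
#' @param smoothness Penalty weight lambda on squared second differences
#'   (default 1e5): larger gives a stiffer baseline.
#' @param asymmetry Asymmetry parameter in (0, 1) (default 0.01): the weight
#'   given to points above the baseline, so peaks barely pull it up.
#' @param max_iter Maximum reweighting iterations (default 10).
#' @return Baseline-corrected [spectral_dataset].
#' @export
awls_baseline <- function(ds, smoothness = 1e5, asymmetry = 0.01,
                          max_iter = 10L) {
  stopifnot(inherits(ds, "spectral_dataset"),
            smoothness > 0, asymmetry > 0, asymmetry < 1, max_iter >= 1)
  p <- n_variables(ds)
  if (p < 3L) stop("awls needs at least 3 variables")
  D <- Matrix::bandSparse(p - 2L, p, k = 0:2,
                          diagonals = list(rep(1, p - 2L), rep(-2, p - 2L),
                                           rep(1, p - 2L)))
  DtD <- Matrix::crossprod(D)
  X <- ds$intensities
  out <- X
  for (i in seq_len(nrow(X)))
    out[i, ] <- X[i, ] - asls_vec(X[i, ], smoothness, asymmetry, max_iter, DtD)
  ds$intensities <- out
  ds
}

#' Peak normalization
#'
#' Divides each spectrum by its intensity at the axis point nearest `peak`
#' (no interpolation); that point becomes exactly 1. The conventional Amide I
#' normalization uses `peak = 1650` cm^-1.
#'
#' @param ds A [spectral_dataset].
#' @param peak Peak position in cm^-1, within the axis range.
#' @return Normalized [spectral_dataset].
#' @export
peak_normalize <- function(ds, peak = 1650) {
  stopifnot(inherits(ds, "spectral_dataset"))
  rng <- range(ds$wavenumbers)
  if (peak < rng[1] || peak > rng[2])
    stop(sprintf("peak %g outside axis range [%g, %g]", peak, rng[1], rng[2]))
  j <- which.min(abs(ds$wavenumbers - peak))
  v <- ds$intensities[, j]
  zero <- which(v == 0)
  if (length(zero) > 0L)
    stop("zero intensity at the peak for sample(s): ",
         paste(ds$sample_ids[utils::head(zero, 3)], collapse = ", "))
  ds$intensities <- ds$intensities / v
  ds
}

#' Vector normalization
#'
#' Scales each spectrum to unit Euclidean norm.
#'
#' @param ds A [spectral_dataset]; no spectrum may be all-zero.
#' @return Normalized [spectral_dataset].
#' @export
vector_normalize <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  nrm <- sqrt(rowSums(ds$intensities^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0L)
    stop("all-zero spectrum cannot be normalized: ",
         paste(ds$sample_ids[utils::head(zero, 3)], collapse = ", "))
  ds$intensities <- ds$intensities / nrm
  ds
}

#' Apply an ordered preprocessing recipe
#'
#' A recipe is a list of steps, each `list(kind = <name>, ...parameters)`
#' with `kind` one of `cut_region`, `savgol`, `rubberband`, `awls`,
#' `peak_norm`, `vector_norm`. Steps run in list order. Recipes can be stored
#' as JSON and loaded with [read_recipe()].
#'
#' @param ds A [spectral_dataset].
#' @param recipe List of step descriptions.
#' @return The preprocessed [spectral_dataset].
#' @examples
#' recipe <- list(list(kind = "cut_region", lo = 900, hi = 1800),
#'                list(kind = "savgol", window = 7, polyorder = 2),
#'                list(kind = "vector_norm"))
#' @export
apply_recipe <- function(ds, recipe) {
  for (step in recipe) {
    kind <- step$kind
    if (is.null(kind)) stop("recipe step without a `kind`")
    ds <- switch(kind,
      cut_region = cut_region(ds, step$lo, step$hi),
      savgol = savgol_smooth(ds, step$window,
                             if (is.null(step$polyorder)) 2L else step$polyorder),
      rubberband = rubberband_baseline(ds),
      awls = awls_baseline(ds,
                           if (is.null(step$smoothness)) 1e5 else step$smoothness,
                           if (is.null(step$asymmetry)) 0.01 else step$asymmetry,
                           if (is.null(step$max_iter)) 10L else step$max_iter),
      peak_norm = peak_normalize(ds, if (is.null(step$peak)) 1650 else step$peak),
      vector_norm = vector_normalize(ds),
      stop("unknown preprocessing step kind: ", kind))
  }
  ds
}

#' Read a preprocessing recipe from JSON
#'
#' @param path Path to a JSON array of step objects.
#' @return A recipe list usable with [apply_recipe()].
#' @export
read_recipe <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
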