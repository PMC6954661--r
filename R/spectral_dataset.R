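# spectral_dataset: the package-wide currency for spectral data.
# Rows are samples, columns are spectral variables on a strictly monotonic
# wavenumber axis; labels are kept as a factor whose level order is
# first-appearance order (used consistently for confusion-matrix layout).

#' Construct a spectral dataset
#'
#' Bundles an intensity matrix (samples x variables), its wavenumber axis,
#' per-sample class labels and sample identifiers into a validated container
#' used by every other function in the package.
#'
#' @param intensities Numeric matrix, `n_samples x n_variables` (absorbance or
#'   counts, arbitrary units). All values must be finite.
#' @param wavenumbers Numeric vector of length `n_variables`, strictly
#'   monotonic (ascending or descending), in cm^-1 (or arbitrary units for
#'   simulated data).
#' @param labels Vector of class identifiers, length `n_samples`. Stored as a
#'   factor with levels in first-appearance order.
#' @param sample_ids Character vector of length `n_samples`; defaults to
#'   `"s1" ... "sn"`.
#'
#' @return An object of class `spectral_dataset` with fields `intensities`,
#'   `wavenumbers`, `labels`, `sample_ids`.
#' @examples
#' ds <- spectral_dataset(matrix(rnorm(12), 3), wavenumbers = c(900, 902, 904, 906),
#'                        labels = c("a", "a", "b"))
#' n_samples(ds)
#' @export
spectral_dataset <- function(intensities, wavenumbers, labels, sample_ids = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (n < 1L || p < 1L)
    stop("empty dataset refused: need at least 1 sample and 1 variable")
  if (!all(is.finite(intensities)))
    stop("non-finite intensities are not allowed")
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != p)
    stop("length(wavenumbers) must equal ncol(intensities)")
  if (p > 1L) {
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumbers must be strictly monotonic")
  }
  if (length(labels) != n)
    stop("length(labels) must equal nrow(intensities)")
  labels <- as.character(labels)
  labels <- factor(labels, levels = unique(labels))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(intensities)")
  dimnames(intensities) <- NULL
  structure(
    list(intensities = intensities, wavenumbers = wavenumbers,
         labels = labels, sample_ids = sample_ids),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d variables\n",
              n_samples(x), n_variables(x)))
  cat(sprintf("  wavenumbers: %g .. %g (%s)\n",
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)],
              if (length(x$wavenumbers) > 1 && diff(x$wavenumbers)[1] < 0)
                "descending" else "ascending"))
  tb <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / variables in a spectral dataset
#' @param ds A `spectral_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$intensities)

#' @rdname n_samples
#' @export
n_variables <- function(ds) ncol(ds$intensities)

#' Select samples from a dataset
#'
#' Returns the dataset restricted to the rows in `idx`, in the order given.
#' The wavenumber axis is carried over unchanged (bitwise).
#'
#' @param ds A `spectral_dataset`.
#' @param idx Integer indices (1-based), no duplicates, all within range.
#' @return A `spectral_dataset` with `length(idx)` samples.
#' @export
subset_samples <- function(ds, idx) {
  stopifnot(inherits(ds, "spectral_dataset"))
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("empty index set refused")
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_samples(ds)))
    stop("index out of range")
  if (anyDuplicated(idx)) stop("duplicate indices not allowed")
  out <- spectral_dataset(ds$intensities[idx, , drop = FALSE],
                          ds$wavenumbers,
                          as.character(ds$labels)[idx],
                          ds$sample_ids[idx])
  out$wavenumbers <- ds$wavenumbers  # exact copy, no numeric round-trip
  out
}

# run expr with a temporary RNG state seeded by `seed`; NULL seed -> use the
# global stream as-is (callers log this).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# round half away from zero (MATLAB-style), used for all sample-count rules
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# one info line per operation; silent unless options(mlmsplit.verbose = TRUE)
log_info <- function(fmt, ...) {
  if (isTRUE(getOption("mlmsplit.verbose", FALSE)))
    message(sprintf(paste0("[mlmsplit] ", fmt), ...))
  invisible(NULL)
}
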