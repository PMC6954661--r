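# Train/test splitters: random selection (RS), Kennard-Stone (KS) and the
# Morais-Lima-Martin (MLM) random-mutation variant. By default each class is
# split independently (per_class = TRUE) so class proportions survive the
# split; all tie-breaks are by lowest sample index for determinism.

#' Splitting configuration
#'
#' @param train_fraction Fraction of each selection pool assigned to training;
#'   default 0.7 (a 70/30 split).
#' @param mutation_factor Fraction of the mutation base exchanged between
#'   training and test after a KS split (MLM only); default 0.10.
#' @param per_class If `TRUE` (default) the splitter runs independently within
#'   each class; if `FALSE` it runs on the pooled data.
#' @param seed Optional integer seed for the stochastic splitters (RS and the
#'   mutation step of MLM). `NULL` draws from the session RNG stream.
#' @param mutation_base Pool whose size the mutation count is computed from:
#'   `"test"` (default), `"train"` or `"total"`. With the defaults the count
#'   per pool is `round(0.10 * |test pool|)`.
#' @return A list of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.7, mutation_factor = 0.10,
                         per_class = TRUE, seed = NULL,
                         mutation_base = c("test", "train", "total")) {
  stopifnot(is.numeric(train_fraction), length(train_fraction) == 1L,
            train_fraction > 0, train_fraction < 1,
            is.numeric(mutation_factor), length(mutation_factor) == 1L,
            mutation_factor >= 0, mutation_factor < 1,
            is.logical(per_class), length(per_class) == 1L)
  mutation_base <- match.arg(mutation_base)
  structure(list(train_fraction = train_fraction,
                 mutation_factor = mutation_factor,
                 per_class = per_class, seed = seed,
                 mutation_base = mutation_base),
            class = "split_config")
}

# selection pools: list of global index vectors, one per class (level order)
# or a single pool when per_class = FALSE
selection_pools <- function(ds, per_class) {
  if (per_class) split(seq_len(n_samples(ds)), ds$labels)
  else list(all = seq_len(n_samples(ds)))
}

# training count for a pool of size n: round half away from zero, then clamp
# so both train and test keep at least one sample
pool_train_count <- function(n, fraction) {
  r <- as.integer(round_half_away(fraction * n))
  max(1L, min(r, n - 1L))
}

new_split_result <- function(train_idx, test_idx, method, cfg) {
  structure(list(train_idx = as.integer(train_idx),
                 test_idx = as.integer(test_idx),
                 method = method,
                 train_fraction = cfg$train_fraction,
                 mutation_factor = if (method == "MLM") cfg$mutation_factor else 0,
                 per_class = cfg$per_class,
                 seed = cfg$seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> method=%s train=%d test=%d (fraction %.2f%s%s)\n",
              x$method, length(x$train_idx), length(x$test_idx),
              x$train_fraction,
              if (x$method == "MLM")
                sprintf(", mutation %.2f", x$mutation_factor) else "",
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

check_pool_sizes <- function(ds, cfg) {
  pools <- selection_pools(ds, cfg$per_class)
  small <- vapply(pools, length, 1L) < 2L
  if (any(small))
    stop("each selection pool needs at least 2 samples; too small: ",
         paste(names(pools)[small], collapse = ", "))
  pools
}

#' Random-selection (RS) split
#'
#' Assigns samples uniformly at random to training and test, honouring the
#' per-pool training counts implied by `train_fraction`. Deterministic given
#' `cfg$seed`.
#'
#' @param ds A [spectral_dataset].
#' @param cfg A [split_config].
#' @return A `split_result` with disjoint `train_idx` / `test_idx` covering
#'   all samples. Indices are 1-based; train and test indices are in
#'   ascending (file) order within each pool.
#' @export
random_split <- function(ds, cfg = split_config()) {
  pools <- check_pool_sizes(ds, cfg)
  res <- with_seed(cfg$seed, lapply(pools, function(pool) {
    ntr <- pool_train_count(length(pool), cfg$train_fraction)
    tr <- sort(sample(pool, ntr))
    list(train = tr, test = setdiff(pool, tr))
  }))
  sr <- new_split_result(unlist(lapply(res, `[[`, "train")),
                         unlist(lapply(res, `[[`, "test")),
                         "RS", cfg)
  assert_valid_split(ds, sr)
  log_info("RS split: n=%d train=%d seed=%s", n_samples(ds),
           length(sr$train_idx), if (is.null(cfg$seed)) "none" else cfg$seed)
  sr
}

# Kennard-Stone max-min selection inside one pool. Returns local indices of
# the selected (training) samples in selection order. D is the pool's
# Euclidean distance matrix. n_sel = 1 degenerates to the lower-indexed
# endpoint of the maximum-distance pair.
ks_select <- function(D, n_sel) {
  n <- nrow(D)
  stopifnot(n_sel >= 1L, n_sel < n)
  # seed with the maximum-distance pair; ties -> lowest (i, j)
  m <- max(D)
  cand <- which(D == m, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  if (n_sel == 1L) return(cand[1, 1])
  sel <- c(cand[1, 1], cand[1, 2])
  in_sel <- logical(n)
  in_sel[sel] <- TRUE
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_sel) {
    rest <- which(!in_sel)
    nxt <- rest[which.max(mind[rest])]  # which.max -> first max = lowest index
    sel <- c(sel, nxt)
    in_sel[nxt] <- TRUE
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Kennard-Stone (KS) split
#'
#' Within each selection pool, the first two training picks are the pair of
#' samples realising the maximum pairwise Euclidean distance; each subsequent
#' pick maximises the minimum distance to the already-selected set (max-min
#' criterion) until the training count is reached. The remaining samples form
#' the test set. Fully deterministic: no seed is consumed and ties are broken
#' by lowest sample index.
#'
#' @inheritParams random_split
#' @return A `split_result`; `train_idx` is in KS selection order (pool by
#'   pool), `test_idx` ascending within each pool.
#' @export
kennard_stone_split <- function(ds, cfg = split_config()) {
  pools <- check_pool_sizes(ds, cfg)
  res <- lapply(pools, function(pool) {
    ntr <- pool_train_count(length(pool), cfg$train_fraction)
    D <- as.matrix(stats::dist(ds$intensities[pool, , drop = FALSE]))
    sel <- ks_select(D, ntr)
    list(train = pool[sel], test = setdiff(pool, pool[sel]))
  })
  sr <- new_split_result(unlist(lapply(res, `[[`, "train")),
                         unlist(lapply(res, `[[`, "test")),
                         "KS", cfg)
  assert_valid_split(ds, sr)
  log_info("KS split: n=%d train=%d (deterministic)", n_samples(ds),
           length(sr$train_idx))
  sr
}

#' Morais-Lima-Martin (MLM) split
#'
#' Computes the KS split, then applies a random mutation: within each
#' selection pool, `m = round(mutation_factor * |base pool|)` distinct
#' train/test pairs are exchanged, chosen uniformly at random without
#' replacement (base pool: see `mutation_base` in [split_config()], default
#' the test pool). Set sizes are unchanged, so the train fraction is exactly
#' preserved. Deterministic given `cfg$seed`. With `mutation_factor = 0` the
#' result equals [kennard_stone_split()] exactly.
#'
#' Swapped-out training samples join the test set; swapped-in test samples
#' are appended at the end of the pool's training selection order.
#'
#' @inheritParams random_split
#' @return A `split_result` with `method = "MLM"`.
#' @export
mlm_split <- function(ds, cfg = split_config()) {
  ks <- kennard_stone_split(ds, cfg)
  if (cfg$mutation_factor == 0) {
    sr <- ks
    sr$method <- "MLM"
    sr$mutation_factor <- 0
    sr$seed <- cfg$seed
    return(sr)
  }
  pools <- selection_pools(ds, cfg$per_class)
  res <- with_seed(cfg$seed, lapply(pools, function(pool) {
    tr <- ks$train_idx[ks$train_idx %in% pool]  # keeps selection order
    te <- ks$test_idx[ks$test_idx %in% pool]
    base_n <- switch(cfg$mutation_base,
                     test = length(te), train = length(tr),
                     total = length(pool))
    m <- as.integer(round_half_away(cfg$mutation_factor * base_n))
    m <- min(m, length(tr), length(te))
    if (m == 0L) {
      warning("mutation count is 0 for a pool of size ", length(pool),
              "; returning the KS assignment for it")
      return(list(train = tr, test = te))
    }
    out <- sample(tr, m)          # train -> test
    inn <- sample(te, m)          # test -> train
    list(train = c(setdiff(tr, out), inn),
         test = sort(c(setdiff(te, inn), out)))
  }))
  sr <- new_split_result(unlist(lapply(res, `[[`, "train")),
                         unlist(lapply(res, `[[`, "test")),
                         "MLM", cfg)
  assert_valid_split(ds, sr)
  log_info("MLM split: n=%d train=%d mutation=%.2f seed=%s", n_samples(ds),
           length(sr$train_idx), cfg$mutation_factor,
           if (is.null(cfg$seed)) "none" else cfg$seed)
  sr
}

#' Validate a split against a dataset
#'
#' Checks the partition invariants (train and test disjoint, their union
#' covering every sample exactly once) and, when the split was made per
#' class, that each class contributes `round(train_fraction * n_c)` training
#' samples (clamped so both sets stay nonempty).
#'
#' @param ds A [spectral_dataset].
#' @param sr A `split_result`.
#' @return `TRUE` if all invariants hold, otherwise `FALSE` with the reasons
#'   in `attr(, "reasons")`.
#' @export
validate_split <- function(ds, sr) {
  reasons <- character(0)
  n <- n_samples(ds)
  tr <- sr$train_idx
  te <- sr$test_idx
  if (anyDuplicated(tr) || anyDuplicated(te))
    reasons <- c(reasons, "duplicate indices within a set")
  if (length(intersect(tr, te)) > 0L)
    reasons <- c(reasons, "train and test sets overlap")
  if (!setequal(union(tr, te), seq_len(n)))
    reasons <- c(reasons, "train and test do not cover all samples exactly")
  if (length(reasons) == 0L) {
    pools <- selection_pools(ds, isTRUE(sr$per_class))
    for (nm in names(pools)) {
      pool <- pools[[nm]]
      want <- pool_train_count(length(pool), sr$train_fraction)
      got <- sum(tr %in% pool)
      if (got != want)
        reasons <- c(reasons, sprintf(
          "pool '%s': %d training samples, expected %d", nm, got, want))
    }
  }
  ok <- length(reasons) == 0L
  if (!ok) attr(ok, "reasons") <- reasons
  ok
}

assert_valid_split <- function(ds, sr) {
  ok <- validate_split(ds, sr)
  if (!isTRUE(ok))
    stop("internal error: invalid split produced (",
         paste(attr(ok, "reasons"), collapse = "; "), ")")
  invisible(sr)
}

#' Serialize / deserialize a split as JSON
#'
#' Archives a `split_result` (1-based indices, method, train fraction,
#' mutation factor, seed) so a split can be stored alongside results and
#' re-applied later with [subset_samples()].
#'
#' @param sr A `split_result`.
#' @param path Output (or input) JSON path.
#' @return `write_split` returns `path` invisibly; `read_split` returns the
#'   `split_result`.
#' @export
write_split <- function(sr, path) {
  stopifnot(inherits(sr, "split_result"))
  jsonlite::write_json(
    list(train_idx = sr$train_idx, test_idx = sr$test_idx,
         method = sr$method, train_fraction = sr$train_fraction,
         mutation_factor = sr$mutation_factor, per_class = sr$per_class,
         seed = sr$seed, index_base = 1L),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_idx = as.integer(x$train_idx),
                 test_idx = as.integer(x$test_idx),
                 method = x$method,
                 train_fraction = x$train_fraction,
                 mutation_factor = x$mutation_factor,
                 per_class = isTRUE(x$per_class),
                 seed = x$seed),
            class = "split_result")
}
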