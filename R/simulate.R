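# Synthetic benchmark: a two-class multiplicative-normal generator and the
# Monte-Carlo comparison of RS/KS/MLM splitting through the PCA-LDA pipeline.
#
# Generator, per simulation (MATLAB randn semantics, no clipping):
#   class 1: A .* B          with A, B iid N(0,1), n_obs x n_vars
#   class 2: (A + shift) .* B
# The shift is applied BEFORE the elementwise product, so both classes have
# entrywise mean 0; class 2 differs in variance (1 + shift^2 per entry, 26 at
# the default shift of 5). Defaults: 100 observations x 1000 variables per
# class, shift 5, 1000 simulations, 70/30 split, 10% mutation.

#' Simulation benchmark configuration
#'
#' Defaults mirror the standard protocol: two classes of 100 observations x
#' 1000 variables, pre-multiplication shift 5, 1000 simulations, 70/30
#' split with 10% mutation, PC count chosen per simulation by 10-fold
#' venetian-blinds CV.
#'
#' @param n_obs_per_class Observations per class (default 100).
#' @param n_vars Variables per observation (default 1000).
#' @param shift Shift added to the first normal factor of class 2 before the
#'   elementwise product (default 5); `shift = 0` makes the classes
#'   distributionally identical.
#' @param n_sims Number of Monte-Carlo repetitions (default 1000).
#' @param train_fraction,mutation_factor Passed to [split_config()].
#' @param max_pcs Largest PC count considered by the CV (default 20; reduce
#'   for speed).
#' @param n_splits Venetian-blinds folds (default 10).
#' @param methods Subset of `c("RS", "KS", "MLM")`.
#' @param master_seed Integer seed from which all per-simulation seeds are
#'   derived (counter-based, so each simulation is individually replayable).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_obs_per_class = 100L, n_vars = 1000L, shift = 5,
                       n_sims = 1000L, train_fraction = 0.7,
                       mutation_factor = 0.10, max_pcs = 20L, n_splits = 10L,
                       methods = c("RS", "KS", "MLM"), master_seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_obs_per_class >= 2L, n_vars >= 2L, n_sims >= 1L)
  structure(list(n_obs_per_class = as.integer(n_obs_per_class),
                 n_vars = as.integer(n_vars), shift = shift,
                 n_sims = as.integer(n_sims),
                 train_fraction = train_fraction,
                 mutation_factor = mutation_factor,
                 max_pcs = as.integer(max_pcs),
                 n_splits = as.integer(n_splits),
                 methods = methods,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# counter-based seed derivation, kept below 2^31
derive_seed <- function(master_seed, sim, role = 0L) {
  as.integer((as.double(master_seed) * 48271 + sim * 3L + role) %% 2147483629)
}

#' Generate the two-class multiplicative-normal dataset
#'
#' Class 1 is the elementwise product of two independent standard-normal
#' matrices; class 2 multiplies `(standard normal + shift)` with an
#' independent standard normal. No clipping is applied. The wavenumber axis
#' is `1..n_vars` in arbitrary units.
#'
#' @param n_obs_per_class Observations per class (>= 2).
#' @param n_vars Variables (>= 2).
#' @param shift Pre-multiplication shift for class 2 (default 5).
#' @param seed Optional integer seed.
#' @return A [spectral_dataset] with classes `"class_1"`, `"class_2"`.
#' @export
generate_two_classes <- function(n_obs_per_class = 100L, n_vars = 1000L,
                                 shift = 5, seed = NULL) {
  stopifnot(n_obs_per_class >= 2L, n_vars >= 2L)
  n <- as.integer(n_obs_per_class); p <- as.integer(n_vars)
  X <- with_seed(seed, {
    c1 <- matrix(stats::rnorm(n * p), n, p) * matrix(stats::rnorm(n * p), n, p)
    c2 <- (matrix(stats::rnorm(n * p), n, p) + shift) *
          matrix(stats::rnorm(n * p), n, p)
    rbind(c1, c2)
  })
  spectral_dataset(X, seq_len(p),
                   rep(c("class_1", "class_2"), each = n),
                   c(paste0("c1_", seq_len(n)), paste0("c2_", seq_len(n))))
}

#' Run the Monte-Carlo splitter benchmark
#'
#' Per simulation: generate a fresh two-class dataset; for each method split
#' it (70/30 per class by default), fit the PCA-LDA pipeline on the training
#' set (PC count by venetian-blinds CV), predict the test set, and record
#' test accuracy plus class-1 sensitivity and specificity. Individual
#' simulation failures are recorded and skipped; more than 1% failures
#' aborts.
#'
#' @param cfg A [sim_config].
#' @param progress Print a dot every 25 simulations (default `FALSE`).
#' @return An object of class `benchmark_result`: per method a list with
#'   `accuracy` (percent vector of length `n_sims`), `sensitivity`,
#'   `specificity`, `mean`, `min`, `max` and `histogram` (width-2 percent
#'   bins); plus `config`, `seeds` and `failures`.
#' @export
run_benchmark <- function(cfg = sim_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- cfg$methods
  acc <- sens <- spec <- lapply(stats::setNames(methods, methods),
                                function(m) rep(NA_real_, cfg$n_sims))
  seeds <- integer(cfg$n_sims)
  failures <- list()
  for (s in seq_len(cfg$n_sims)) {
    seeds[s] <- derive_seed(cfg$master_seed, s, 0L)
    res <- tryCatch({
      ds <- generate_two_classes(cfg$n_obs_per_class, cfg$n_vars, cfg$shift,
                                 seed = seeds[s])
      out <- list()
      for (m in methods) {
        scfg <- split_config(train_fraction = cfg$train_fraction,
                             mutation_factor = cfg$mutation_factor,
                             seed = derive_seed(cfg$master_seed, s,
                                                match(m, c("RS", "KS", "MLM"))))
        sr <- switch(m,
                     RS = random_split(ds, scfg),
                     KS = kennard_stone_split(ds, scfg),
                     MLM = mlm_split(ds, scfg))
        model <- fit_pca_lda(subset_samples(ds, sr$train_idx),
                             max_pcs = cfg$max_pcs, n_splits = cfg$n_splits)
        test <- subset_samples(ds, sr$test_idx)
        rep_ <- evaluation_report(test$labels, predict(model, test),
                                  class_order = levels(ds$labels))
        out[[m]] <- c(acc = rep_$accuracy,
                      sens = unname(rep_$sensitivity[1]),
                      spec = unname(rep_$specificity[1]))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(sim = s, seed = seeds[s],
                                                message = conditionMessage(res))
      if (length(failures) > max(1, 0.01 * cfg$n_sims))
        stop("more than 1% of simulations failed; last error: ",
             conditionMessage(res))
      next
    }
    for (m in methods) {
      acc[[m]][s] <- res[[m]]["acc"]
      sens[[m]][s] <- res[[m]]["sens"]
      spec[[m]][s] <- res[[m]]["spec"]
    }
    if (progress && s %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  per_method <- lapply(stats::setNames(methods, methods), function(m) {
    a <- acc[[m]][!is.na(acc[[m]])]
    lo <- min(50, 2 * floor(min(a) / 2))
    hi <- max(85, 2 * ceiling(max(a) / 2))
    h <- graphics::hist(a, breaks = seq(lo, hi, by = 2), plot = FALSE)
    list(accuracy = acc[[m]], sensitivity = sens[[m]], specificity = spec[[m]],
         mean = mean(a), min = min(a), max = max(a),
         histogram = list(breaks = h$breaks, counts = h$counts))
  })
  structure(list(methods = per_method, config = cfg, seeds = seeds,
                 failures = failures),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d simulations (%dx%d per class, shift %g)\n",
              x$config$n_sims, x$config$n_obs_per_class, x$config$n_vars,
              x$config$shift))
  for (m in names(x$methods)) {
    mm <- x$methods[[m]]
    cat(sprintf("  %-3s mean accuracy %.1f%% (range %.0f-%.0f%%)\n",
                m, mm$mean, mm$min, mm$max))
  }
  if (length(x$failures) > 0)
    cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Write a benchmark result as JSON
#'
#' @param bench A `benchmark_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  stopifnot(inherits(bench, "benchmark_result"))
  jsonlite::write_json(
    list(config = unclass(bench$config),
         methods = bench$methods,
         seeds = bench$seeds,
         n_failures = length(bench$failures)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Small deterministic fixture datasets
#'
#' Generates compact datasets for unit testing and examples: either two
#' Gaussian blobs separated along a fixed direction, or the two-class
#' multiplicative-normal generator at reduced size.
#'
#' @param n_per_class Samples per class (>= 2, <= 50 recommended).
#' @param n_vars Variables (>= 2, <= 50 recommended).
#' @param type `"blobs"` (default) or `"product"`.
#' @param separation Mean separation between blob centers in units of the
#'   unit noise SD (default 6; only for `type = "blobs"`).
#' @param seed Optional integer seed.
#' @return A [spectral_dataset] with two classes.
#' @export
make_fixture <- function(n_per_class = 10L, n_vars = 10L,
                         type = c("blobs", "product"), separation = 6,
                         seed = NULL) {
  type <- match.arg(type)
  if (n_per_class < 2L) stop("need at least 2 samples per class")
  if (n_vars < 2L) stop("need at least 2 variables")
  if (type == "product")
    return(generate_two_classes(n_per_class, n_vars, shift = 5, seed = seed))
  n <- as.integer(n_per_class); p <- as.integer(n_vars)
  X <- with_seed(seed, {
    c1 <- matrix(stats::rnorm(n * p), n, p)
    c2 <- matrix(stats::rnorm(n * p), n, p)
    c2[, 1] <- c2[, 1] + separation
    rbind(c1, c2)
  })
  spectral_dataset(X, seq_len(p),
                   rep(c("class_1", "class_2"), each = n))
}
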