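#' Specification of a synthetic benchmark dataset
#'
#' Describes a Gaussian regression dataset emulating the regimes of real
#' benchmark collections: tall (p < n) through wide (p > n) shapes,
#' correlated standardized predictors, sparse coefficient vectors, and a
#' generating-model population R-squared dialed to a target in roughly the
#' 0.5-0.9 range.
#'
#' @param n,p sample size and number of candidate predictors.
#' @param correlation `"independent"`, `"ar1"` (corr \eqn{\rho^{|i-j|}}),
#'   `"block"` (equicorrelated blocks), or `"factor"` (shared latent
#'   factors).
#' @param rho correlation parameter for `"ar1"`/`"block"` (|rho| < 1;
#'   `"block"` needs rho in \[0, 1)).
#' @param block_size block width for `"block"`.
#' @param n_factors number of latent factors for `"factor"`.
#' @param true_support_size number of nonzero coefficients.
#' @param effect_scale magnitude of the nonzero coefficients (signs random).
#' @param decay if `TRUE`, magnitudes decay geometrically (ratio
#'   `decay_ratio`) so weak-but-real effects are present.
#' @param decay_ratio geometric ratio of successive effect magnitudes
#'   (default 0.8).
#' @param target_r2 population R-squared of the generating model, in (0, 1).
#' @param seed integer seed.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n, p, correlation = c("independent", "ar1",
                                                 "block", "factor"),
                           rho = 0.5, block_size = 10, n_factors = 3,
                           true_support_size = 5, effect_scale = 1,
                           decay = FALSE, decay_ratio = 0.8,
                           target_r2 = 0.7, seed = 1) {
  correlation <- match.arg(correlation)
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must lie in (0, 1)")
  if (true_support_size > min(p, n - 2))
    stop("true_support_size must be <= min(p, n - 2)")
  if (correlation %in% c("ar1", "block")) {
    if (abs(rho) >= 1) stop("|rho| must be < 1")
    if (correlation == "block" && rho < 0)
      stop("block correlation needs rho in [0, 1)")
  }
  structure(list(n = n, p = p, correlation = correlation, rho = rho,
                 block_size = block_size, n_factors = n_factors,
                 true_support_size = true_support_size,
                 effect_scale = effect_scale, decay = decay,
                 decay_ratio = decay_ratio,
                 target_r2 = target_r2, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a correlated Gaussian design
#'
#' Draws the predictors with the requested correlation structure and then
#' standardizes each column empirically (mean 0, variance 1), matching the
#' preprocessing applied to real datasets. Deterministic per spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return Standardized n x p design matrix.
#' @export
generate_design <- function(spec) {
  set.seed(derive_seed(spec$seed, "design"))
  n <- spec$n; p <- spec$p
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- switch(spec$correlation,
    independent = Z,
    ar1 = {
      X <- Z
      for (j in 2:p)
        X[, j] <- spec$rho * X[, j - 1L] + sqrt(1 - spec$rho^2) * Z[, j]
      X
    },
    block = {
      nb <- ceiling(p / spec$block_size)
      f <- matrix(stats::rnorm(n * nb), n, nb)
      blk <- rep(seq_len(nb), each = spec$block_size)[seq_len(p)]
      sqrt(spec$rho) * f[, blk, drop = FALSE] + sqrt(1 - spec$rho) * Z
    },
    factor = {
      k <- spec$n_factors
      f <- matrix(stats::rnorm(n * k), n, k)
      L <- matrix(stats::rnorm(p * k, sd = 1 / sqrt(k)), p, k)
      load2 <- rowSums(L^2)
      f %*% t(L) + Z * rep(sqrt(pmax(1 - pmin(load2, 0.9), 0.1)), each = n)
    })
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Draw the data-generating truth for a synthetic design
#'
#' Support positions are drawn uniformly; nonzero coefficients are
#' `effect_scale` in magnitude (geometrically decaying if requested) with
#' random signs. The noise SD solves analytically for the target
#' R-squared using the realized design covariance: with signal variance
#' \eqn{v = \mathrm{var}(X\beta)}, \eqn{\sigma = \sqrt{v (1 - R^2) / R^2}}.
#'
#' @param spec a [synthetic_spec()].
#' @param design matrix from [generate_design()].
#' @return A `"generating_model"` (see [select_generating_model()]) with
#'   `alpha_DG = 0`.
#' @export
make_true_model <- function(spec, design) {
  s <- spec$true_support_size
  if (s == 0) stop("target_r2 is unattainable with an empty support")
  set.seed(derive_seed(spec$seed, "truth"))
  p <- spec$p
  support_idx <- sort(sample.int(p, s))
  mags <- spec$effect_scale *
    (if (spec$decay) spec$decay_ratio^(seq_len(s) - 1L) else rep(1, s))
  beta <- numeric(p)
  beta[support_idx] <- mags * sample(c(-1, 1), s, replace = TRUE)
  signal <- drop(design %*% beta)
  v <- stats::var(signal)
  sigma <- sqrt(v * (1 - spec$target_r2) / spec$target_r2)
  support <- as.integer(seq_len(p) %in% support_idx)
  nms <- colnames(design)
  structure(list(support = stats::setNames(support, nms),
                 beta_DG = stats::setNames(beta, nms),
                 alpha_DG = 0, sigma_DG = sigma,
                 r2_source = spec$target_r2),
            class = "generating_model")
}

.preset_specs <- function(seed) {
  list(
    tall_small = synthetic_spec(n = 500, p = 15, correlation = "ar1",
                                rho = 0.5, true_support_size = 8,
                                decay = TRUE, decay_ratio = 0.7,
                                target_r2 = 0.8,
                                seed = derive_seed(seed, "tall_small")),
    tall_large = synthetic_spec(n = 2000, p = 30, correlation = "ar1",
                                rho = 0.5, true_support_size = 12,
                                decay = TRUE, decay_ratio = 0.7,
                                target_r2 = 0.7,
                                seed = derive_seed(seed, "tall_large")),
    square = synthetic_spec(n = 150, p = 100, correlation = "ar1",
                            rho = 0.5, true_support_size = 10,
                            decay = TRUE, decay_ratio = 0.7,
                            target_r2 = 0.7,
                            seed = derive_seed(seed, "square")),
    wide = synthetic_spec(n = 60, p = 300, correlation = "ar1",
                          rho = 0.5, true_support_size = 8,
                          decay = TRUE, decay_ratio = 0.7,
                          target_r2 = 0.8,
                          seed = derive_seed(seed, "wide")))
}

#' Generate a named benchmark dataset suite
#'
#' Four presets span the empirically observed regimes: `tall_small`
#' (n = 500, p = 15), `tall_large` (n = 2000, p = 30), `square`
#' (n = 150, p = 100) and `wide` (n = 60, p = 300; p > n). Each preset
#' carries its standardized design, generating truth, and a matrix of
#' parametric-bootstrap replicate responses, all reproducible from the
#' seed.
#'
#' @param preset one of `"tall_small"`, `"tall_large"`, `"square"`,
#'   `"wide"`; ignored when `spec` is given.
#' @param seed integer seed.
#' @param n_reps number of bootstrap replicates to pre-wire (default 100).
#' @param spec optional custom [synthetic_spec()] replacing the preset;
#'   `name` labels the resulting dataset.
#' @param name dataset label for a custom `spec` (default `"custom"`).
#' @return Object of class `"benchmark_dataset"`: `name`, `spec`, `X`
#'   (standardized design), `truth` (a `"generating_model"`), `Y`
#'   (n x n_reps replicate responses).
#' @export
generate_benchmark_suite <- function(preset = c("tall_small", "tall_large",
                                                "square", "wide"),
                                     seed = 1, n_reps = 100, spec = NULL,
                                     name = "custom") {
  if (is.null(spec)) {
    preset <- match.arg(preset)
    spec <- .preset_specs(seed)[[preset]]
  } else {
    stopifnot(inherits(spec, "synthetic_spec"))
    preset <- name
  }
  X <- generate_design(spec)
  truth <- make_true_model(spec, X)
  Y <- parametric_bootstrap(truth, X, n_reps = n_reps,
                            seed = derive_seed(spec$seed, "bootstrap"))
  structure(list(name = preset, spec = spec, X = X, truth = truth, Y = Y),
            class = "benchmark_dataset")
}

#' @export
#' @method print benchmark_dataset
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("benchmark dataset '%s': n = %d, p = %d, |support| = %d, %d replicates\n",
              x$name, x$spec$n, x$spec$p, sum(x$truth$support), ncol(x$Y)))
  invisible(x)
}

#' Write a synthetic dataset and its manifest
#'
#' Writes one replicate as CSV (response column `y`) plus a JSON manifest
#' of the spec and seed, sufficient for exact regeneration.
#'
#' @param suite a `"benchmark_dataset"`.
#' @param dir output directory (created if needed).
#' @param replicate which replicate response to write (default 1).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_dataset <- function(suite, dir, replicate = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(suite$name, ".csv"))
  df <- data.frame(y = suite$Y[, replicate], suite$X, check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  manifest <- file.path(dir, paste0(suite$name, "_manifest.json"))
  writeLines(jsonlite::toJSON(c(unclass(suite$spec), list(replicate = replicate)),
                              auto_unbox = TRUE, digits = NA), manifest)
  invisible(c(csv, manifest))
}
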