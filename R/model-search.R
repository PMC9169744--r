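#' Posterior over the model space by exact enumeration
#'
#' Scores all \eqn{2^p} submodels under a g-prior and a model-space prior and
#' normalizes with log-sum-exp. Models that are rank deficient or larger than
#' \eqn{n-2} receive prior mass zero. Feasible only for small p; beyond
#' `max_p` use [mc3_sample()].
#'
#' @param data a [regression_data] object.
#' @param gspec a [gprior()] specification (default JZS).
#' @param mprior a [model_prior()] specification.
#' @param max_p refusal threshold for enumeration (default 25).
#' @return An object of class `"model_posterior"` with elements `models`
#'   (binary matrix, one row per retained model), `posterior_mass`,
#'   `log_marginal`, `log_prior`, `r2`, `d`, `inclusion_prob` (exact, from
#'   all \eqn{2^p} models), `method = "enumeration"`.
#' @examples
#' d <- regression_data(cbind(h = c(62.5, 67.5, 70.5)), c(64.5, 69.5, 72.5))
#' post <- enumerate_posterior(d, gprior("fixed", g = "sqrt-n"),
#'                             model_prior("uniform"))
#' post$posterior_mass  # odds 1.65 : 1 for the one-predictor model
#' @export
enumerate_posterior <- function(data, gspec = gprior("jzs"),
                                mprior = model_prior("beta-binomial"),
                                max_p = 25) {
  p <- data$p
  if (p > max_p)
    stop("p = ", p, " exceeds the enumeration cap (", max_p,
         "); use mc3_sample() instead")
  ws <- gram_workspace(data)
  vg <- .variant_code(gspec, data$n, p)
  pk <- .prior_code(mprior, data$n)
  res <- .enumerate_cpp(ws$XtX, ws$Xty, ws$tss, data$n,
                        vg$variant, vg$g, vg$a, pk$kind, pk$max_size)
  lp <- res$log_marginal + res$log_prior
  lz <- logsumexp(lp)
  mass <- exp(lp - lz)
  idx <- 0:(2^p - 1)
  inclusion <- vapply(seq_len(p), function(j)
    sum(mass[bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L]), numeric(1))
  # retain models covering all but a negligible sliver of posterior mass
  ord <- order(mass, decreasing = TRUE)
  keep <- ord[seq_len(max(which(cumsum(mass[ord]) >= 1 - 1e-12)[1], 1L))]
  bits <- vapply(idx[keep], function(i)
    as.integer(bitwAnd(i, bitwShiftL(1L, 0:(p - 1L))) != 0L), integer(p))
  models <- if (p == 1L) matrix(bits, ncol = 1L) else t(bits)
  colnames(models) <- data$column_names
  structure(list(models = models,
                 posterior_mass = mass[keep] / sum(mass[keep]),
                 log_marginal = res$log_marginal[keep],
                 log_prior = res$log_prior[keep],
                 r2 = res$r2[keep], d = res$d[keep],
                 inclusion_prob = stats::setNames(inclusion, data$column_names),
                 method = "enumeration", n_iterations = NA_integer_,
                 n_models_scored = length(idx), p = p, n = data$n,
                 gprior = gspec, modelprior = mprior),
            class = "model_posterior")
}

#' Posterior over the model space by MC3 sampling
#'
#' Markov chain Monte Carlo model composition: a Metropolis–Hastings random
#' walk on inclusion vectors whose proposal mixes, with equal probability, a
#' single-coordinate add/delete move and a random swap between a currently
#' included and a currently excluded variable (the swap falls back to
#' add/delete at the empty and full models). Posterior model masses and
#' inclusion probabilities are estimated by visit frequencies over the whole
#' chain (no burn-in by default); renormalized-marginal masses over the
#' unique visited models are kept alongside as a diagnostic.
#'
#' @inheritParams enumerate_posterior
#' @param n_iter number of MCMC iterations (default 10000).
#' @param seed integer seed; the chain is deterministic given (data, seed).
#' @return A `"model_posterior"` (see [enumerate_posterior()]) with
#'   `method = "mc3"`, visit-frequency `posterior_mass` and
#'   `inclusion_prob`, plus `renorm_mass` and `accept_rate`.
#' @export
mc3_sample <- function(data, gspec = gprior("jzs"),
                       mprior = model_prior("beta-binomial"),
                       n_iter = 10000, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (data$p < 1) stop("no candidate predictors")
  ws <- gram_workspace(data)
  vg <- .variant_code(gspec, data$n, data$p)
  pk <- .prior_code(mprior, data$n)
  set.seed(as.integer(seed))
  res <- .mc3_cpp(ws$XtX, ws$Xty, ws$tss, data$n,
                  vg$variant, vg$g, vg$a, pk$kind, pk$max_size,
                  as.integer(n_iter))
  visited <- res$visits > 0L
  lp <- res$log_marginal[visited] + res$log_prior[visited]
  renorm <- exp(lp - logsumexp(lp))
  models <- res$models[visited, , drop = FALSE]
  colnames(models) <- data$column_names
  structure(list(models = models,
                 posterior_mass = res$visits[visited] / sum(res$visits),
                 log_marginal = res$log_marginal[visited],
                 log_prior = res$log_prior[visited],
                 r2 = res$r2[visited], d = res$d[visited],
                 inclusion_prob = stats::setNames(res$inclusion_freq,
                                                  data$column_names),
                 renorm_mass = renorm, accept_rate = res$accept_rate,
                 method = "mc3", n_iterations = as.integer(n_iter),
                 n_models_scored = nrow(res$models), p = data$p, n = data$n,
                 gprior = gspec, modelprior = mprior),
            class = "model_posterior")
}

#' @export
#' @method print model_posterior
print.model_posterior <- function(x, n_show = 5, ...) {
  cat(sprintf("model posterior (%s): %d distinct models, p = %d\n",
              x$method, nrow(x$models), x$p))
  ord <- order(x$posterior_mass, decreasing = TRUE)[seq_len(min(n_show, nrow(x$models)))]
  for (i in ord) {
    vars <- colnames(x$models)[x$models[i, ] == 1L]
    cat(sprintf("  P = %.4f  {%s}\n", x$posterior_mass[i],
                if (length(vars)) paste(vars, collapse = ", ") else "null"))
  }
  invisible(x)
}

#' Maximum a posteriori model
#'
#' Returns the inclusion vector of the highest-posterior-mass model. Ties are
#' broken toward the smaller model, then lexicographically on the inclusion
#' vector.
#'
#' @param post a `"model_posterior"`.
#' @return Named binary inclusion vector of length p.
#' @export
map_model <- function(post) {
  stopifnot(inherits(post, "model_posterior"))
  mass <- post$posterior_mass
  if (!length(mass)) stop("empty posterior")
  best <- which(mass == max(mass))
  if (length(best) > 1L) {
    best <- best[order(post$d[best],
                       apply(post$models[best, , drop = FALSE], 1L,
                             paste, collapse = ""))]
  }
  stats::setNames(post$models[best[1L], ], colnames(post$models))
}

#' Serialize a model posterior to JSON
#'
#' Writes models as bit strings with their log marginals, priors and masses,
#' plus inclusion probabilities, for reuse outside R.
#'
#' @param post a `"model_posterior"`.
#' @param file optional path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `file`.
#' @export
posterior_to_json <- function(post, file = NULL) {
  obj <- list(method = post$method,
              gamma = apply(post$models, 1L, paste, collapse = ""),
              log_marginal = post$log_marginal,
              log_prior = post$log_prior,
              posterior_mass = post$posterior_mass,
              inclusion_prob = as.list(post$inclusion_prob))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

# map spec objects to the integer codes the C++ layer uses
.variant_code <- function(gspec, n, p) {
  stopifnot(inherits(gspec, "gprior_spec"))
  code <- match(gspec$variant,
                c("fixed", "hyper-g", "eb-local", "jzs", "bic", "aic")) - 1L
  g <- if (gspec$variant == "fixed") resolve_g(gspec, n, p) else 0
  list(variant = code, g = g, a = gspec$hyper_a)
}

.prior_code <- function(mprior, n) {
  stopifnot(inherits(mprior, "model_prior_spec"))
  kind <- match(mprior$kind, c("uniform", "beta-binomial", "truncated")) - 1L
  m <- mprior$max_size
  if (is.null(m)) m <- n - 2L
  list(kind = kind, max_size = as.integer(m))
}
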