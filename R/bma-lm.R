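#' Bayesian model averaging for linear regression
#'
#' Fits the full BMA machinery for the normal linear model
#' \deqn{y = \alpha 1_n + X\beta + \epsilon, \qquad \epsilon \sim N(0,
#' \sigma^2 I),} with a Zellner g-prior family prior on the coefficients of
#' each submodel, a flat prior \eqn{\pi(\alpha,\sigma) \propto \sigma^{-1}}
#' on intercept and error scale, and a model-space prior over the \eqn{2^p}
#' inclusion vectors. Predictors are standardized and the response centered
#' on entry, so all Bayes factors depend on the data only through each
#' model's \eqn{R^2}. The posterior over models comes from exact enumeration
#' (small p) or MC3 sampling.
#'
#' @param x design matrix (default method) or a formula.
#' @param ... further arguments passed to the default method.
#' @return An object of class `"bma_lm"`: a list with the standardized
#'   `data`, the `posterior` (a `"model_posterior"`), the `gprior` and
#'   `modelprior` specifications, and the matched `call`. Methods:
#'   [print.bma_lm()], [summary.bma_lm()], [coef.bma_lm()],
#'   [predict.bma_lm()], [plot.bma_lm()]; see also [bma_coefficients()],
#'   [bma_predict()], [bms()] and [map_model()].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200, 5)
#' y <- X[, 1] - 0.8 * X[, 3] + rnorm(200)
#' fit <- bma_lm(X, y, prior = "g-sqrt-n", seed = 2)
#' fit
#' coef(fit)
#' @export
bma_lm <- function(x, ...) UseMethod("bma_lm")

#' @rdname bma_lm
#' @param y response vector (default method).
#' @param prior a method label understood by [gprior_method()] (e.g.
#'   `"JZS"`, `"g-sqrt-n"`, `"hyper-g"`, `"EB-local"`) or a [gprior()]
#'   specification. Default `"JZS"`, the usual reference prior.
#' @param modelprior `"auto"` (beta-binomial(1, 1); truncated at `n - 2`
#'   when `p > n`) or a [model_prior()] specification.
#' @param method `"auto"` (enumerate when `p <= enumerate_cutoff`, else
#'   MC3), `"enumerate"`, or `"mc3"`.
#' @param n_iter MC3 chain length (default 10000).
#' @param seed integer seed used by MC3 (deterministic chain per seed).
#' @param enumerate_cutoff largest p for which `"auto"` enumerates
#'   (default 12).
#' @param standardize standardize the inputs (see [regression_data()]).
#' @export
bma_lm.default <- function(x, y, prior = "JZS", modelprior = "auto",
                           method = c("auto", "enumerate", "mc3"),
                           n_iter = 10000, seed = 1, enumerate_cutoff = 12,
                           standardize = TRUE, ...) {
  method <- match.arg(method)
  data <- if (inherits(x, "regression_data")) x
          else regression_data(x, y, standardize = standardize)
  gspec <- if (is.character(prior)) gprior_method(prior) else prior
  stopifnot(inherits(gspec, "gprior_spec"))
  mprior <- if (identical(modelprior, "auto")) {
    if (data$p > data$n) model_prior("truncated") else model_prior("beta-binomial")
  } else modelprior
  stopifnot(inherits(mprior, "model_prior_spec"))
  if (method == "auto")
    method <- if (data$p <= enumerate_cutoff) "enumerate" else "mc3"
  post <- if (method == "enumerate")
    enumerate_posterior(data, gspec, mprior)
  else mc3_sample(data, gspec, mprior, n_iter = n_iter, seed = seed)
  structure(list(data = data, posterior = post, gprior = gspec,
                 modelprior = mprior, prior_label = if (is.character(prior))
                   prior else gspec$variant,
                 selection = "BMA", call = match.call()),
            class = "bma_lm")
}

#' @rdname bma_lm
#' @param formula a model formula; the full candidate set is the right-hand
#'   side, the response the left-hand side.
#' @param data a data frame for the formula interface.
#' @export
bma_lm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- bma_lm.default(X, y, ...)
  fit$call <- match.call()
  fit
}

#' @export
#' @method print bma_lm
print.bma_lm <- function(x, ...) {
  cat("Bayesian model averaging, linear regression\n")
  cat(sprintf("  prior: %s | model prior: %s | search: %s%s\n",
              x$prior_label, x$modelprior$kind, x$posterior$method,
              if (x$posterior$method == "mc3")
                sprintf(" (%d iterations)", x$posterior$n_iterations) else ""))
  cat(sprintf("  n = %d, p = %d; %s\n", x$data$n, x$data$p,
              if (x$selection == "MAP") "conditioned on the MAP model"
              else sprintf("%d models retained", nrow(x$posterior$models))))
  ip <- sort(x$posterior$inclusion_prob, decreasing = TRUE)
  top <- utils::head(ip, 8L)
  cat("  top inclusion probabilities:\n")
  for (v in names(top)) cat(sprintf("    %-12s %.3f\n", v, top[[v]]))
  invisible(x)
}

#' @export
#' @method coef bma_lm
coef.bma_lm <- function(object, ...) {
  .analytic_coef_mean(object$data, object$posterior, object$gprior)
}

#' Summarize a BMA fit
#'
#' @param object a [bma_lm] fit.
#' @param alpha,n_draws,seed see [bma_coefficients()].
#' @param ... unused.
#' @return A `"bma_coef"` coefficient summary.
#' @export
#' @method summary bma_lm
summary.bma_lm <- function(object, alpha = 0.05, n_draws = 10000, seed = 1,
                           ...) {
  bma_coefficients(object, alpha = alpha, n_draws = n_draws, seed = seed)
}

#' @export
#' @method print bma_coef
print.bma_coef <- function(x, digits = 4, ...) {
  cat("BMA coefficient summary (posterior means, equal-tailed intervals)\n")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Predict from a BMA fit
#'
#' @param object a [bma_lm] fit.
#' @param newdata matrix of predictor rows on the original input scale.
#' @param interval `"none"` for point predictions, `"prediction"` for
#'   posterior predictive intervals.
#' @param alpha,n_draws,seed see [bma_predict()].
#' @param ... unused.
#' @return Numeric vector of point predictions, or a `"bma_prediction"`
#'   when intervals are requested.
#' @export
#' @method predict bma_lm
predict.bma_lm <- function(object, newdata, interval = c("none", "prediction"),
                           alpha = 0.05, n_draws = 10000, seed = 1, ...) {
  interval <- match.arg(interval)
  res <- bma_predict(object, newdata, alpha = alpha, n_draws = n_draws,
                     seed = seed,
                     interval = if (interval == "none") "none" else "prediction")
  if (interval == "none") res$point else res
}

#' Plot posterior inclusion probabilities
#'
#' @param x a [bma_lm] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
#' @method plot bma_lm
plot.bma_lm <- function(x, ...) {
  ip <- x$posterior$inclusion_prob
  graphics::barplot(ip, las = 2, ylim = c(0, 1),
                    ylab = "posterior inclusion probability", ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
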