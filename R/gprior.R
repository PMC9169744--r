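#' Zellner g-prior specifications
#'
#' Constructs the specification of a coefficient prior for Bayesian model
#' averaging in linear regression. Under model \eqn{M_\gamma} the g-prior is
#' \deqn{\beta_\gamma \mid \alpha, \sigma^2 \sim N(0, g\,\sigma^2 (X_\gamma^T
#' X_\gamma)^{-1}), \qquad \pi(\alpha, \sigma) \propto \sigma^{-1},}
#' so every Bayes factor against the null (intercept-only) model is a function
#' of the model's \eqn{R^2}, its size \eqn{d}, the sample size \eqn{n} and
#' \eqn{g}. Supported variants:
#' \describe{
#'   \item{`fixed`}{fixed g chosen by `g`: `"sqrt-n"` (\eqn{g=\sqrt n}),
#'     `"n"` (unit-information prior), `"one"` (\eqn{g=1}), `"benchmark"`
#'     (\eqn{g=\max\{n,p^2\}}), or a positive number.}
#'   \item{`hyper-g`}{continuous prior \eqn{\pi(g) \propto (1+g)^{-a/2}} with
#'     hyperparameter `hyper_a` (> 2, default 3).}
#'   \item{`eb-local`}{empirical Bayes, g estimated per model as
#'     \eqn{\hat g = \max(F-1, 0)} from the model's F statistic.}
#'   \item{`jzs`}{Jeffreys–Zellner–Siow: Cauchy coefficient prior, i.e. an
#'     inverse-gamma(1/2, n/2) mixture over g.}
#'   \item{`bic`, `aic`}{information-criterion approximations to the model
#'     weights.}
#' }
#'
#' @param variant one of `"fixed"`, `"hyper-g"`, `"eb-local"`, `"jzs"`,
#'   `"bic"`, `"aic"`.
#' @param g for `variant = "fixed"`: a rule name or a positive number.
#' @param hyper_a hyper-g hyperparameter a (> 2).
#' @return An object of class `"gprior_spec"`.
#' @seealso [log_marginal()], [bma_lm()]
#' @export
gprior <- function(variant = c("fixed", "hyper-g", "eb-local", "jzs", "bic", "aic"),
                   g = "sqrt-n", hyper_a = 3) {
  variant <- match.arg(variant)
  if (variant == "fixed") {
    if (is.character(g)) {
      if (!g %in% c("sqrt-n", "n", "one", "benchmark"))
        stop("unknown g rule: ", g)
    } else if (!is.numeric(g) || length(g) != 1L || g <= 0) {
      stop("numeric g must be a single positive value")
    }
  }
  if (variant == "hyper-g" && hyper_a <= 2) stop("hyper_a must exceed 2")
  structure(list(variant = variant, g_rule = g, hyper_a = hyper_a),
            class = "gprior_spec")
}

#' @export
#' @method print gprior_spec
print.gprior_spec <- function(x, ...) {
  extra <- switch(x$variant,
                  fixed = paste0(" (g rule: ", format(x$g_rule), ")"),
                  `hyper-g` = paste0(" (a = ", x$hyper_a, ")"), "")
  cat("g-prior spec: ", x$variant, extra, "\n", sep = "")
  invisible(x)
}

#' Map a benchmark method label to a g-prior spec
#'
#' Labels follow the usual naming in the model-uncertainty literature:
#' `"JZS"`, `"g-sqrt-n"`, `"hyper-g"`, `"EB-local"`, `"UIP"` (g = n),
#' `"g-1"`, `"benchmark"`, `"BIC"`, `"AIC"`.
#'
#' @param label a method label.
#' @return A `"gprior_spec"`.
#' @export
gprior_method <- function(label) {
  switch(label,
         "JZS"       = gprior("jzs"),
         "g-sqrt-n"  = gprior("fixed", g = "sqrt-n"),
         "hyper-g"   = gprior("hyper-g"),
         "EB-local"  = gprior("eb-local"),
         "UIP"       = gprior("fixed", g = "n"),
         "g-1"       = gprior("fixed", g = "one"),
         "benchmark" = gprior("fixed", g = "benchmark"),
         "BIC"       = gprior("bic"),
         "AIC"       = gprior("aic"),
         stop("unknown method label: ", label))
}

#' Resolve the fixed-g rule to a numeric value
#'
#' @param spec a `"gprior_spec"` with `variant = "fixed"` (other variants
#'   return `NA` as they carry no single g).
#' @param n sample size.
#' @param p number of candidate predictors (needed for the benchmark rule
#'   \eqn{g = \max\{n, p^2\}}).
#' @return Positive scalar g.
#' @examples
#' resolve_g(gprior("fixed", g = "sqrt-n"), n = 100, p = 5)  # 10
#' resolve_g(gprior("fixed", g = "benchmark"), n = 50, p = 10)  # 100
#' @export
resolve_g <- function(spec, n, p = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (spec$variant != "fixed") return(NA_real_)
  r <- spec$g_rule
  if (is.numeric(r)) return(as.numeric(r))
  switch(r,
         "sqrt-n" = sqrt(n),
         "n" = as.numeric(n),
         "one" = 1,
         "benchmark" = {
           if (is.null(p)) stop("benchmark rule needs p")
           max(n, p^2)
         },
         stop("unknown g rule: ", r))
}

#' Log Bayes factor against the null model, fixed g
#'
#' Exact closed form: \deqn{\log B = \frac{n-1-d}{2}\log(1+g) -
#' \frac{n-1}{2}\log\{1+g(1-R^2)\}.} Finite for all \eqn{R^2 \in [0,1]}; at
#' \eqn{R^2 = 1} it attains the finite ceiling \eqn{\frac{n-1-d}{2}\log(1+g)}
#' (fixed-g priors bound the evidence even for a perfect fit). The null model
#' (`d = 0`) returns 0.
#'
#' @param r2 model coefficient of determination in `[0, 1]`.
#' @param n sample size.
#' @param d number of included predictors.
#' @param g positive prior scale.
#' @return Log Bayes factor (vectorized over `r2`/`d`).
#' @examples
#' exp(log_bf_fixed_g(1, n = 3, d = 1, g = sqrt(3)))  # 1.6529
#' @export
log_bf_fixed_g <- function(r2, n, d, g) {
  if (any(g <= 0)) stop("g must be positive")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("r2 must lie in [0, 1]")
  r2 <- pmin(pmax(r2, 0), 1)
  out <- ((n - 1 - d) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - r2))
  out[d == 0] <- 0
  out
}

#' Upper bound of the fixed-g Bayes factor
#'
#' Supremum over \eqn{R^2} of [log_bf_fixed_g()], attained at \eqn{R^2 = 1}:
#' \eqn{\frac{n-1-d}{2}\log(1+g)}. This ceiling is typically astronomically
#' large for moderate n (for \eqn{n = 20}, \eqn{d = 1}, \eqn{g = \sqrt{20}} it
#' already exceeds four million), so in practice it does not constrain
#' inference.
#'
#' @inheritParams log_bf_fixed_g
#' @return Log of the maximal Bayes factor.
#' @export
max_log_bf_fixed_g <- function(n, d, g) {
  log_bf_fixed_g(1, n, d, g)
}

# log integral of exp(logf) over (0,1) with max-shift; logf vectorized.
# Segment edges accumulate geometrically toward u = 1, where the mixing
# densities peak for large n (posterior g scale ~ n, so u* ~ 1 - 1/n).
.log_integral01 <- function(logf, rel.tol = 1e-10) {
  edges <- c(0, 0.25, 1 - 2^-(1:18), 1)
  probe <- as.vector(outer(c(0.25, 0.5, 0.75), diff(edges)) +
                       rep(edges[-length(edges)], each = 3L))
  M <- max(logf(probe))
  if (!is.finite(M)) return(if (M > 0) Inf else -Inf)
  f <- function(u) {
    v <- logf(pmin(pmax(u, 1e-12), 1 - 1e-12)) - M
    ifelse(v > -745, exp(v), 0)
  }
  tot <- sum(vapply(seq_along(edges)[-1L], function(i) {
    stats::integrate(f, edges[i - 1L], edges[i], rel.tol = rel.tol,
                     abs.tol = 1e-13, subdivisions = 200L,
                     stop.on.error = FALSE)$value
  }, numeric(1)))
  if (tot <= 0) return(-Inf)
  M + log(tot)
}

#' Log Bayes factor under the hyper-g prior
#'
#' Mixes the fixed-g Bayes factor over \eqn{\pi(g) = \frac{a-2}{2}
#' (1+g)^{-a/2}}; equivalently \eqn{B = \frac{a-2}{d+a-2}\,
#' {}_2F_1\!\big(\frac{n-1}{2}, 1; \frac{d+a}{2}; R^2\big)}. Computed as a
#' one-dimensional integral on \eqn{u = g/(1+g) \in (0,1)} with a log-scale
#' shift, which stays stable for large n where the hypergeometric series
#' overflows. Unlike fixed-g priors the evidence diverges as \eqn{R^2 \to 1}
#' whenever \eqn{d + a \le n + 1} (the resolution of the information paradox).
#'
#' @inheritParams log_bf_fixed_g
#' @param a hyperparameter (> 2), default 3.
#' @return Log Bayes factor; `+Inf` in the divergent perfect-fit case.
#' @export
log_bf_hyper_g <- function(r2, n, d, a = 3) {
  if (a <= 2) stop("a must exceed 2")
  if (length(r2) > 1L || length(d) > 1L)
    return(mapply(log_bf_hyper_g, r2 = r2, d = d, MoreArgs = list(n = n, a = a)))
  if (d == 0) return(0)
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (r2 >= 1) {
    if (d + a <= n + 1) return(Inf)
    return(log(a - 2) - log(d + a - n - 1))
  }
  c1 <- (d + a) / 2 - 2
  c2 <- (n - 1) / 2
  lf <- function(u) c1 * log1p(-u) - c2 * log1p(-u * r2)
  out <- log((a - 2) / 2) + .log_integral01(lf)
  if (is.nan(out)) out <- Inf  # overflow near r2 = 1 reported as divergence
  out
}

#' Log Bayes factor under the local empirical Bayes prior
#'
#' Estimates g within each model by \eqn{\hat g = \max(F - 1, 0)} where
#' \eqn{F = \frac{R^2/d}{(1-R^2)/(n-1-d)}} is the model's F statistic, then
#' plugs \eqn{\hat g} into the fixed-g Bayes factor — i.e. the maximum of the
#' fixed-g evidence over g. Returns 0 whenever \eqn{\hat g = 0} and diverges
#' as \eqn{R^2 \to 1}.
#'
#' @inheritParams log_bf_fixed_g
#' @return Log Bayes factor.
#' @export
log_bf_eb_local <- function(r2, n, d) {
  if (length(r2) > 1L || length(d) > 1L)
    return(mapply(log_bf_eb_local, r2 = r2, d = d, MoreArgs = list(n = n)))
  if (d == 0) return(0)
  if (n - 1 - d <= 0) stop("saturated model: n - 1 - d must be positive")
  if (r2 >= 1) return(Inf)
  Fstat <- (r2 / d) / ((1 - r2) / (n - 1 - d))
  ghat <- max(Fstat - 1, 0)
  if (ghat == 0) return(0)
  log_bf_fixed_g(r2, n, d, ghat)
}

#' Log Bayes factor under the Jeffreys–Zellner–Siow prior
#'
#' The Zellner–Siow Cauchy prior on coefficients is an inverse-gamma(1/2,
#' n/2) mixture over g: \eqn{\pi(g) = \sqrt{n/2}\,\Gamma(1/2)^{-1} g^{-3/2}
#' e^{-n/(2g)}}. The Bayes factor \eqn{\int B_{\mathrm{fixed}}(g)\,\pi(g)\,dg}
#' is evaluated by adaptive quadrature after the substitution
#' \eqn{u = g/(1+g)}, which tames the heavy tail (relative tolerance 1e-10,
#' with a log-scale shift).
#'
#' @inheritParams log_bf_fixed_g
#' @return Log Bayes factor.
#' @export
log_bf_jzs <- function(r2, n, d) {
  if (length(r2) > 1L || length(d) > 1L)
    return(mapply(log_bf_jzs, r2 = r2, d = d, MoreArgs = list(n = n)))
  if (d == 0) return(0)
  if (n - 1 - d <= 0) stop("saturated model: n - 1 - d must be positive")
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  lf <- function(u) {
    g <- u / (1 - u)
    0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n * (1 - u) / (2 * u) +
      (d / 2) * log1p(-u) - ((n - 1) / 2) * log1p(-u * r2) - 2 * log1p(-u)
  }
  .log_integral01(lf)
}

#' Information-criterion log model weights
#'
#' BIC and AIC surrogates for the log Bayes factor against the null model,
#' on the half-deviance scale so that weight differences reproduce the usual
#' criterion differences: BIC gives \eqn{-\{n\log(1-R^2) + d\log n\}/2}, AIC
#' \eqn{-\{n\log(1-R^2) + 2d\}/2}. The per-variable BIC penalty is
#' \eqn{\log n}, twice the \eqn{\log(1+\sqrt n)} penalty of the exact
#' \eqn{g=\sqrt n} Bayes factor.
#'
#' @param criterion `"bic"` or `"aic"`.
#' @inheritParams log_bf_fixed_g
#' @return Log model weight up to a constant shared across models.
#' @export
log_weight_ic <- function(criterion = c("bic", "aic"), r2, n, d) {
  criterion <- match.arg(criterion)
  if (any(r2 >= 1)) {
    warning("r2 = 1: information-criterion weight is divergent (+Inf)")
  }
  pen <- if (criterion == "bic") d * log(n) else 2 * d
  out <- -(n * log1p(-r2) + pen) / 2
  out[rep_len(r2 >= 1, length(out))] <- Inf
  out
}

#' Log marginal likelihood (up to a shared constant) for any variant
#'
#' Dispatches on the g-prior specification; the value is the log Bayes factor
#' of the model against the null model, so the null model is the common
#' anchor at 0 and only differences between models matter.
#'
#' @param spec a [gprior()] specification.
#' @inheritParams log_bf_fixed_g
#' @param p number of candidate predictors (benchmark g rule only).
#' @return Log marginal likelihood relative to the null model.
#' @export
log_marginal <- function(spec, r2, n, d, p = NULL) {
  switch(spec$variant,
         fixed = log_bf_fixed_g(r2, n, d, resolve_g(spec, n, p)),
         `hyper-g` = log_bf_hyper_g(r2, n, d, spec$hyper_a),
         `eb-local` = log_bf_eb_local(r2, n, d),
         jzs = log_bf_jzs(r2, n, d),
         bic = log_weight_ic("bic", r2, n, d),
         aic = log_weight_ic("aic", r2, n, d))
}

#' Model-space prior specification
#'
#' The default is the beta-binomial(1, 1) prior, under which every model
#' size is a priori equally likely: \eqn{P(M_\gamma) = 1/\{(p+1)\binom{p}{d}\}}.
#' The truncated variant additionally assigns probability zero to any model
#' with more than `max_size` predictors (by default \eqn{n-2}, the largest
#' size that leaves the error variance estimable) and renormalizes — the
#' standard choice when \eqn{p > n}. `"uniform"` puts mass \eqn{2^{-p}} on
#' every model.
#'
#' @param kind `"beta-binomial"`, `"uniform"` or `"truncated"`.
#' @param max_size truncation bound for `"truncated"`; `NULL` means `n - 2`
#'   at evaluation time.
#' @return An object of class `"model_prior_spec"`.
#' @export
model_prior <- function(kind = c("beta-binomial", "uniform", "truncated"),
                        max_size = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, max_size = max_size), class = "model_prior_spec")
}

#' Log prior mass of a model of size d
#'
#' @param spec a [model_prior()] specification.
#' @param d model size (number of included predictors).
#' @param p number of candidate predictors.
#' @param n sample size (used for the default truncation bound `n - 2`).
#' @return Log prior mass (vectorized over `d`); `-Inf` for truncated-out
#'   sizes.
#' @examples
#' # beta-binomial(1,1), p = 2: sizes 0,1,1,2 get masses 1/3, 1/6, 1/6, 1/3
#' exp(model_log_prior(model_prior("beta-binomial"), d = 0:2, p = 2, n = 10))
#' @export
model_log_prior <- function(spec, d, p, n = NULL) {
  if (any(d < 0 | d > p)) stop("d must lie in [0, p]")
  switch(spec$kind,
         uniform = rep(-p * log(2), length(d)),
         `beta-binomial` = -log(p + 1) - lchoose(p, d),
         truncated = {
           m <- spec$max_size
           if (is.null(m)) {
             if (is.null(n)) stop("truncated prior needs n or an explicit max_size")
             m <- n - 2L
           }
           m <- min(m, p)
           out <- -log(m + 1) - lchoose(p, d)
           out[d > m] <- -Inf
           out
         })
}
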