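# Posterior draw machinery shared by coefficient summaries and prediction.
#
# Conditional on a model gamma and on g, the coefficient posterior under the
# g-prior with flat pi(alpha, sigma) is multivariate Student-t with n-1
# degrees of freedom, location (g/(1+g)) * OLS, and scale
# (g/(1+g)) * s2_g * (X'X)^{-1} where s2_g = TSS(1 - (g/(1+g)) R^2)/(n-1).
# Draws are generated as sigma^2 ~ InvGamma((n-1)/2, SSR_g/2) then
# beta | sigma^2 ~ Normal. Adaptive variants draw g per draw from its
# conditional posterior p(g | gamma, y) by inverse-CDF on a u = g/(1+g) grid
# (hyper-g, JZS) or use the plug-in empirical Bayes estimate (EB-local).
# BIC/AIC weights carry no g: the unshrunk OLS posterior (flat-prior limit)
# is used for them.

.U_GRID_N <- 1024L

# grid density of u = g/(1+g) given a model; returns midpoints and weights
.u_grid <- function(variant, r2, n, d, a) {
  u <- (seq_len(.U_GRID_N) - 0.5) / .U_GRID_N
  lw <- if (variant == "hyper-g") {
    ((d + a) / 2 - 2) * log1p(-u) - ((n - 1) / 2) * log1p(-u * r2)
  } else {  # jzs
    g <- u / (1 - u)
    -1.5 * log(g) - n * (1 - u) / (2 * u) + (d / 2) * log1p(-u) -
      ((n - 1) / 2) * log1p(-u * r2) - 2 * log1p(-u)
  }
  w <- exp(lw - max(lw))
  list(u = u, w = w / sum(w))
}

.sample_u <- function(grid, k) {
  i <- sample.int(.U_GRID_N, k, replace = TRUE, prob = grid$w)
  pmin(pmax(grid$u[i] + (stats::runif(k) - 0.5) / .U_GRID_N, 1e-12), 1 - 1e-12)
}

# expected shrinkage factor E[g/(1+g) | gamma, y] for the analytic mixture mean
.expected_shrink <- function(gspec, r2, n, d, p) {
  if (d == 0) return(0)
  switch(gspec$variant,
         fixed = { g <- resolve_g(gspec, n, p); g / (1 + g) },
         `eb-local` = {
           gh <- max((r2 / d) / ((1 - r2) / (n - 1 - d)) - 1, 0)
           gh / (1 + gh)
         },
         bic = 1, aic = 1,
         { gr <- .u_grid(gspec$variant, r2, n, d, gspec$hyper_a)
           sum(gr$u * gr$w) })
}

# per-model OLS pieces used by every draw
.model_pieces <- function(data, gamma) {
  sel <- which(gamma == 1L)
  d <- length(sel)
  if (d == 0L) return(list(sel = sel, d = 0L, beta = numeric(0), R = NULL))
  Xs <- data$X[, sel, drop = FALSE]
  R <- chol(crossprod(Xs))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xs, data$y)))
  list(sel = sel, d = d, beta = drop(beta), R = R)
}

# joint draws of (beta, alpha, sigma2, predictions); deterministic given seed
.posterior_draws <- function(data, post, gspec, n_draws, seed,
                             X_new_std = NULL, pred_noise = TRUE) {
  set.seed(as.integer(seed))
  n <- data$n; p <- data$p
  tss <- sum(data$y^2)
  mass <- post$posterior_mass
  pos <- which(mass > 0)
  counts <- drop(stats::rmultinom(1L, n_draws, mass[pos]))
  beta_draws <- matrix(0, n_draws, p,
                       dimnames = list(NULL, data$column_names))
  sigma2 <- numeric(n_draws)
  alpha <- numeric(n_draws)
  preds <- if (!is.null(X_new_std))
    matrix(0, n_draws, nrow(X_new_std)) else NULL
  row0 <- 0L
  for (k in seq_along(pos)) {
    cnt <- counts[k]
    if (cnt == 0L) next
    i <- pos[k]
    pieces <- .model_pieces(data, post$models[i, ])
    d <- pieces$d
    r2 <- if (d > 0) post$r2[i] else 0
    rows <- row0 + seq_len(cnt)
    row0 <- row0 + cnt
    if (gspec$variant %in% c("bic", "aic")) {
      rss <- tss * (1 - r2)
      df <- max(n - 1 - d, 1L)
      s2 <- rss / 2 / stats::rgamma(cnt, df / 2)
      bmat <- if (d > 0) {
        Z <- matrix(stats::rnorm(d * cnt), d, cnt)
        pieces$beta + backsolve(pieces$R, Z) * rep(sqrt(s2), each = d)
      }
    } else {
      shrink <- if (d == 0) rep(0, cnt) else switch(
        gspec$variant,
        fixed = { g <- resolve_g(gspec, n, p); rep(g / (1 + g), cnt) },
        `eb-local` = {
          gh <- max((r2 / d) / ((1 - r2) / (n - 1 - d)) - 1, 0)
          rep(gh / (1 + gh), cnt)
        },
        .sample_u(.u_grid(gspec$variant, r2, n, d, gspec$hyper_a), cnt))
      ssr <- tss * (1 - shrink * r2)
      s2 <- ssr / 2 / stats::rgamma(cnt, (n - 1) / 2)
      bmat <- if (d > 0) {
        Z <- matrix(stats::rnorm(d * cnt), d, cnt)
        outer(pieces$beta, shrink) +
          backsolve(pieces$R, Z) * rep(sqrt(s2 * shrink), each = d)
      }
    }
    sigma2[rows] <- s2
    alpha[rows] <- stats::rnorm(cnt, 0, sqrt(s2 / n))
    if (d > 0) beta_draws[rows, pieces$sel] <- t(bmat)
    if (!is.null(preds)) {
      mu <- alpha[rows] + if (d > 0)
        t(X_new_std[, pieces$sel, drop = FALSE] %*% bmat) else 0
      if (pred_noise)
        mu <- mu + matrix(stats::rnorm(cnt * nrow(X_new_std), 0,
                                       rep(sqrt(s2), nrow(X_new_std))),
                          cnt, nrow(X_new_std))
      preds[rows, ] <- mu
    }
  }
  list(beta = beta_draws, sigma2 = sigma2, alpha = alpha, pred = preds)
}

# analytic mass-weighted mixture mean of the coefficients
.analytic_coef_mean <- function(data, post, gspec) {
  out <- numeric(data$p)
  pos <- which(post$posterior_mass > 0)
  for (i in pos) {
    gamma <- post$models[i, ]
    if (sum(gamma) == 0L) next
    pieces <- .model_pieces(data, gamma)
    t_m <- .expected_shrink(gspec, post$r2[i], data$n, pieces$d, data$p)
    out[pieces$sel] <- out[pieces$sel] +
      post$posterior_mass[i] * t_m * pieces$beta
  }
  stats::setNames(out, data$column_names)
}

#' Model-averaged coefficient summary
#'
#' Posterior means (analytic mass-weighted mixture means) and equal-tailed
#' `1 - alpha` credible intervals of the coefficients under the full model
#' mixture, the exclusion point mass at zero included. Intervals are Monte
#' Carlo quantiles from `n_draws` seeded draws.
#'
#' @param fit a [bma_lm] fit.
#' @param alpha interval miscoverage level (default 0.05 for 95% intervals).
#' @param n_draws number of posterior draws (default 10000; fewer than 1000
#'   triggers a warning about interval Monte Carlo error).
#' @param seed integer seed for the draws.
#' @return A data frame of class `"bma_coef"` with columns `variable`,
#'   `mean`, `lower`, `upper`, `inclusion_prob`.
#' @export
bma_coefficients <- function(fit, alpha = 0.05, n_draws = 10000, seed = 1) {
  stopifnot(inherits(fit, "bma_lm"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_draws < 1000) warning("n_draws < 1000: interval Monte Carlo error ",
                              "will be substantial")
  dr <- .posterior_draws(fit$data, fit$posterior, fit$gprior, n_draws, seed)
  qs <- apply(dr$beta, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- data.frame(variable = fit$data$column_names,
                    mean = .analytic_coef_mean(fit$data, fit$posterior,
                                               fit$gprior),
                    lower = qs[1L, ], upper = qs[2L, ],
                    inclusion_prob = as.numeric(fit$posterior$inclusion_prob),
                    row.names = NULL)
  class(out) <- c("bma_coef", "data.frame")
  out
}

#' Write a coefficient summary to CSV
#'
#' @param x a `"bma_coef"` summary.
#' @param file output path.
#' @export
write_coefficients_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Model-averaged prediction
#'
#' Point predictions are the mixture predictive means; interval bounds are
#' equal-tailed quantiles of seeded draws of (model, g, coefficients,
#' intercept, noise), i.e. posterior predictive intervals.
#'
#' @param fit a [bma_lm] fit.
#' @param newdata matrix of new predictor rows on the original input scale
#'   (standardized internally with the training constants).
#' @param alpha interval miscoverage level.
#' @param n_draws,seed Monte Carlo draw controls.
#' @param interval `"prediction"` for predictive intervals (new-observation
#'   noise included) or `"none"` for point predictions only.
#' @return A list of class `"bma_prediction"` with `point`, and when
#'   intervals are requested `lower`, `upper` at level `1 - alpha`.
#' @export
bma_predict <- function(fit, newdata, alpha = 0.05, n_draws = 10000,
                        seed = 1, interval = c("prediction", "none")) {
  stopifnot(inherits(fit, "bma_lm"))
  interval <- match.arg(interval)
  Xs <- standardize_newdata(fit$data, newdata)
  mean_beta <- .analytic_coef_mean(fit$data, fit$posterior, fit$gprior)
  point <- drop(Xs %*% mean_beta) + fit$data$y_center
  if (interval == "none")
    return(structure(list(point = point), class = "bma_prediction"))
  dr <- .posterior_draws(fit$data, fit$posterior, fit$gprior, n_draws, seed,
                         X_new_std = Xs, pred_noise = TRUE)
  qs <- apply(dr$pred, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(point = point,
                 lower = qs[1L, ] + fit$data$y_center,
                 upper = qs[2L, ] + fit$data$y_center),
            class = "bma_prediction")
}

#' Condition a BMA fit on its MAP model
#'
#' Collapses the model posterior onto the maximum a posteriori model, turning
#' model averaging into model selection: every downstream summary
#' ([bma_coefficients()], [bma_predict()], `coef`, `predict`) then conditions
#' on that single model.
#'
#' @param fit a [bma_lm] fit.
#' @return A `"bma_lm"` object whose posterior puts mass 1 on the MAP model.
#' @export
bms <- function(fit) {
  stopifnot(inherits(fit, "bma_lm"))
  post <- fit$posterior
  gam <- map_model(post)
  i <- which(apply(post$models, 1L, function(r) all(r == gam)))[1L]
  post$models <- post$models[i, , drop = FALSE]
  post$posterior_mass <- 1
  post$log_marginal <- post$log_marginal[i]
  post$log_prior <- post$log_prior[i]
  post$r2 <- post$r2[i]
  post$d <- post$d[i]
  post$inclusion_prob <- stats::setNames(as.numeric(gam), names(gam))
  fit$posterior <- post
  fit$selection <- "MAP"
  fit
}

#' MAP-model (selection) inference
#'
#' Convenience wrapper: coefficient summary and predictions conditioned on
#' the MAP model only.
#'
#' @inheritParams bma_predict
#' @return List with elements `coefficients` (a `"bma_coef"`) and
#'   `prediction` (a `"bma_prediction"`, `NULL` when `newdata` is missing).
#' @export
bms_infer <- function(fit, newdata = NULL, alpha = 0.05, n_draws = 10000,
                      seed = 1) {
  sel <- bms(fit)
  list(coefficients = bma_coefficients(sel, alpha, n_draws, seed),
       prediction = if (!is.null(newdata))
         bma_predict(sel, newdata, alpha, n_draws, seed))
}
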