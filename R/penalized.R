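#' Largest useful lasso penalty
#'
#' \eqn{\lambda_{\max} = \max_j |x_j^T y| / (n \cdot \mathrm{mix})}: the
#' smallest penalty at which no variable enters the model (under the
#' objective \eqn{\frac{1}{2n}\|y - X\beta\|^2 + \lambda P(\beta)} with
#' convex-mixing weight `mix` on the l1 part).
#'
#' @param data a [regression_data] object.
#' @param mix elastic-net mixing weight in (0, 1]; 1 is the lasso.
#' @return Positive scalar.
#' @export
lambda_max <- function(data, mix = 1) {
  if (mix <= 0 || mix > 1) stop("mix must lie in (0, 1]")
  max(abs(crossprod(data$X, data$y))) / (data$n * mix)
}

.lambda_grid <- function(data, mix = 1, n_lambda = 100, ratio = 1e-4) {
  lmax <- lambda_max(data, mix)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Penalized-likelihood baseline fits
#'
#' Cross-validated lasso and elastic net through a fixed contract: a
#' 100-point log-spaced penalty grid from \eqn{\lambda_{\max}} down to
#' \eqn{10^{-4}\lambda_{\max}}, K-fold cross-validation, selection by the
#' CV-risk minimizer (`"lasso"`, `"elastic-net"`) or the one-standard-error
#' rule (`"lasso-1se"`, the sparsest penalty within one SE of the minimum).
#' The elastic net additionally tunes its convex-mixing weight over
#' \{0.25, 0.5, 0.75\} with shared folds. The inner coordinate-descent
#' solver is glmnet.
#'
#' @param data a [regression_data] object.
#' @param method `"lasso"`, `"lasso-1se"` or `"elastic-net"`.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `"penalized_fit"`: `coefficients` (length p,
#'   exact zeros preserved), `lambda_selected`, `rule`, `mix`, `path`
#'   (list with `lambda` and a p x nlambda coefficient matrix), `y_center`.
#' @export
fit_penalized <- function(data, method = c("lasso", "lasso-1se", "elastic-net"),
                          n_folds = 10, seed = 1) {
  method <- match.arg(method)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (sum(data$y^2) == 0) stop("response is constant")
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(n_folds), data$n))
  fit_one <- function(mix) {
    grid <- .lambda_grid(data, mix)
    glmnet::cv.glmnet(data$X, data$y, lambda = grid, alpha = mix,
                      foldid = foldid, standardize = FALSE, intercept = FALSE)
  }
  if (method == "elastic-net") {
    mixes <- c(0.25, 0.5, 0.75)
    cvs <- lapply(mixes, fit_one)
    best <- which.min(vapply(cvs, function(cv) min(cv$cvm), numeric(1)))
    cv <- cvs[[best]]
    mix <- mixes[best]
    rule <- "cv_min"
  } else {
    cv <- fit_one(1)
    mix <- 1
    rule <- if (method == "lasso-1se") "cv_1se" else "cv_min"
  }
  lam <- if (rule == "cv_1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = lam))[-1L]  # drop intercept slot
  beta[abs(beta) < 1e-10] <- 0  # restore exact sparsity lost to solver fuzz
  path_beta <- as.matrix(cv$glmnet.fit$beta)
  path_beta[abs(path_beta) < 1e-10] <- 0
  structure(list(coefficients = stats::setNames(beta, data$column_names),
                 lambda_selected = lam, rule = rule, mix = mix, method = method,
                 path = list(lambda = cv$glmnet.fit$lambda, beta = path_beta),
                 cvm = cv$cvm, lambda_grid = cv$lambda,
                 y_center = data$y_center, column_names = data$column_names),
            class = "penalized_fit")
}

#' @export
#' @method print penalized_fit
print.penalized_fit <- function(x, ...) {
  cat(sprintf("%s fit (rule %s, mix %.2f): lambda = %.5g, %d nonzero of %d\n",
              x$method, x$rule, x$mix, x$lambda_selected,
              sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' @export
#' @method coef penalized_fit
coef.penalized_fit <- function(object, ...) object$coefficients

#' @export
#' @method predict penalized_fit
predict.penalized_fit <- function(object, newdata, data = NULL, ...) {
  Xs <- if (!is.null(data)) standardize_newdata(data, newdata) else as.matrix(newdata)
  drop(Xs %*% object$coefficients) + object$y_center
}

#' Coefficient path over a penalty grid
#'
#' Solves the penalized problem at every grid value and returns the
#' coefficient vectors; the per-penalty support sets are what the
#' precision-recall sweep for variable selection consumes.
#'
#' @param data a [regression_data] object.
#' @param method `"lasso"` or `"elastic-net"` (mixing weight 0.5).
#' @param lambda_grid strictly positive, descending penalty grid; default
#'   the standard 100-point grid.
#' @return List with `lambda` and `beta` (p x nlambda matrix).
#' @export
coefficient_path <- function(data, method = c("lasso", "elastic-net"),
                             lambda_grid = NULL) {
  method <- match.arg(method)
  mix <- if (method == "lasso") 1 else 0.5
  if (is.null(lambda_grid)) lambda_grid <- .lambda_grid(data, mix)
  if (any(lambda_grid <= 0)) stop("lambda grid must be strictly positive")
  if (is.unsorted(rev(lambda_grid), strictly = FALSE) && length(lambda_grid) > 1L)
    stop("lambda grid must be descending")
  fit <- glmnet::glmnet(data$X, data$y, lambda = lambda_grid, alpha = mix,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-10)
  beta <- as.matrix(stats::coef(fit, s = lambda_grid, exact = FALSE))[-1L, ,
                                                                      drop = FALSE]
  beta[abs(beta) < 1e-10] <- 0  # solver fuzz below working precision
  rownames(beta) <- data$column_names
  list(lambda = lambda_grid, beta = beta)
}

#' Support path as a binary matrix
#'
#' @param path a [coefficient_path()] result.
#' @return p x nlambda binary matrix of inclusion indicators.
#' @export
support_path <- function(path) {
  (path$beta != 0) * 1L
}
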