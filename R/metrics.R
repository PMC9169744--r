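#' Root mean squared error of coefficient estimates
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\tfrac1p \sum_{i=1}^p (\beta_{i,DG} -
#' \hat\beta_i)^2}} against the data-generating coefficients.
#'
#' @param beta_true,beta_hat numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
rmse_coefficients <- function(beta_true, beta_hat) {
  if (length(beta_true) != length(beta_hat))
    stop("coefficient vectors differ in length")
  sqrt(mean((beta_true - beta_hat)^2))
}

#' Interval score
#'
#' Proper score for a central `1 - alpha` interval \eqn{[l, u]} of a target
#' z: \deqn{\mathrm{IS}_\alpha(l, u, z) = (u - l) + \tfrac{2}{\alpha}(l - z)
#' 1\{z < l\} + \tfrac{2}{\alpha}(z - u) 1\{z > u\}.} Width plus weighted
#' exceedance penalties; lower is better.
#'
#' @param l,u interval bounds, `l <= u` (vectorized).
#' @param z realized target value(s).
#' @param alpha miscoverage level in (0, 1), default 0.05.
#' @return Nonnegative score(s).
#' @examples
#' interval_score(0, 1, 1.5)  # 1 + 40 * 0.5 = 21
#' @export
interval_score <- function(l, u, z, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(l > u + 1e-12)) stop("lower bound exceeds upper bound")
  (u - l) + (2 / alpha) * (l - z) * (z < l) + (2 / alpha) * (z - u) * (z > u)
}

#' Mean interval score
#'
#' Arithmetic mean of [interval_score()] over coefficient or prediction
#' targets; the IntEst and IntPred summary.
#'
#' @param lower,upper vectors of interval bounds.
#' @param z vector of realized targets.
#' @param alpha miscoverage level.
#' @return Scalar MIS.
#' @export
mean_interval_score <- function(lower, upper, z, alpha = 0.05) {
  if (!length(z)) stop("no targets supplied")
  if (length(lower) != length(z) || length(upper) != length(z))
    stop("bounds and targets differ in length")
  mean(interval_score(lower, upper, z, alpha))
}

#' Area under the precision-recall curve for support recovery
#'
#' Measures how well a method ranks the truly active variables above the
#' inactive ones without fixing an inclusion threshold. Two input modes:
#' continuous `scores` (e.g. posterior inclusion probabilities), swept over
#' every distinct threshold (tie groups enter as one threshold), or a binary
#' support `path` (e.g. lasso supports along the penalty grid from
#' \eqn{\lambda_{\max}} downward). Area by step integration at the
#' achievable recalls (average-precision convention, no interpolation);
#' with constant scores the curve collapses to the single point
#' (recall 1, precision = prevalence) and the area equals the prevalence.
#'
#' @param true_support binary vector with at least one positive.
#' @param scores numeric variable scores (higher = more likely active).
#' @param path p x L binary matrix of supports (columns ordered from the
#'   strongest penalty to the weakest).
#' @return Area in `[0, 1]`.
#' @export
auprc <- function(true_support, scores = NULL, path = NULL) {
  truth <- as.integer(true_support != 0)
  npos <- sum(truth)
  if (npos == 0) stop("true_support has no positives; recall undefined")
  if (is.null(scores) == is.null(path))
    stop("supply exactly one of scores or path")
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) stop("scores length mismatch")
    pr <- vapply(sort(unique(scores), decreasing = TRUE), function(th) {
      sel <- scores >= th
      c(sum(truth[sel]) / npos, sum(truth[sel]) / sum(sel))
    }, numeric(2))
  } else {
    if (nrow(path) != length(truth)) stop("path row count mismatch")
    sizes <- colSums(path != 0)
    pr <- vapply(which(sizes > 0), function(j) {
      sel <- path[, j] != 0
      c(sum(truth[sel]) / npos, sum(truth[sel]) / sum(sel))
    }, numeric(2))
    if (!length(pr)) return(0)
  }
  rec <- pr[1L, ]; prec <- pr[2L, ]
  ord <- order(rec, -prec)
  rec <- rec[ord]; prec <- prec[ord]
  keep <- !duplicated(rec)  # at equal recall keep the best precision
  rec <- rec[keep]; prec <- prec[keep]
  sum(diff(c(0, rec)) * prec)
}

#' Test-set prediction R-squared
#'
#' \deqn{R^2_{\mathrm{test}} = 1 - \frac{\sum_{i \in \mathrm{test}} (y_i -
#' \hat y_i)^2}{\sum_{i \in \mathrm{test}} (y_i - \bar y_{\mathrm{train}})^2},}
#' comparing predictions against the train-mean baseline; can be negative
#' when the method predicts worse than that baseline.
#'
#' @param y_test test responses.
#' @param y_pred predictions.
#' @param train_mean mean of the training responses.
#' @return Scalar `<= 1`.
#' @export
r2_test <- function(y_test, y_pred, train_mean) {
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  denom <- sum((y_test - train_mean)^2)
  if (denom <= 0) stop("test responses are constant at the train mean")
  1 - sum((y_test - y_pred)^2) / denom
}

#' Average model size
#'
#' For a model posterior: the expected model size \eqn{\sum_j
#' P(\gamma_j = 1 \mid y)}. For a penalized fit: the count of nonzero
#' coefficients. A list is averaged elementwise (the per-replicate mean
#' \eqn{\hat p}).
#'
#' @param x a `"model_posterior"`, `"bma_lm"`, `"penalized_fit"`, numeric
#'   coefficient vector, or list thereof.
#' @return Nonnegative scalar.
#' @export
average_model_size <- function(x) {
  if (inherits(x, "bma_lm")) x <- x$posterior
  if (inherits(x, "model_posterior")) return(sum(x$inclusion_prob))
  if (inherits(x, "penalized_fit")) return(sum(x$coefficients != 0))
  if (is.numeric(x)) return(sum(x != 0))
  if (is.list(x)) {
    if (!length(x)) stop("empty input")
    return(mean(vapply(x, average_model_size, numeric(1))))
  }
  stop("unsupported input")
}
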