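#' Standardized regression data
#'
#' Bundles a design matrix and response in the form every downstream routine
#' expects: continuous predictor columns standardized to mean zero and unit
#' variance, response centered at zero. The centering/scaling constants are
#' retained so that new observations (e.g. a test split) can be put on the
#' training scale.
#'
#' @param X numeric matrix (n x p) of candidate predictors.
#' @param y numeric response vector of length n.
#' @param standardize logical; standardize columns of `X` and center `y`
#'   (default `TRUE`). With `FALSE` the inputs must already satisfy the
#'   invariants (checked).
#' @return An object of class `"regression_data"`: a list with elements `X`,
#'   `y`, `n`, `p`, `column_names`, `x_center`, `x_scale`, `y_center`.
#' @examples
#' d <- regression_data(matrix(rnorm(60), 20, 3), rnorm(20))
#' colMeans(d$X)  # ~ 0
#' @export
regression_data <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  if (standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2L, stats::sd)
    if (any(x_scale <= 0)) stop("constant predictor column(s): ",
                                paste(cn[x_scale <= 0], collapse = ", "))
    X <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
    y_center <- mean(y)
    y <- y - y_center
  } else {
    x_center <- rep(0, p); x_scale <- rep(1, p); y_center <- 0
    if (p > 0 && max(abs(colMeans(X))) > 1e-8)
      stop("X columns must have mean 0 when standardize = FALSE")
    if (p > 0 && max(abs(apply(X, 2L, stats::var) - 1)) > 1e-6)
      stop("X columns must have variance 1 when standardize = FALSE")
    if (abs(mean(y)) > 1e-8) stop("y must be centered when standardize = FALSE")
  }
  structure(list(X = X, y = y, n = n, p = p, column_names = cn,
                 x_center = x_center, x_scale = x_scale, y_center = y_center),
            class = "regression_data")
}

#' @export
#' @method print regression_data
print.regression_data <- function(x, ...) {
  cat(sprintf("regression_data: n = %d, p = %d (standardized X, centered y)\n",
              x$n, x$p))
  invisible(x)
}

#' Read a delimited dataset as regression data
#'
#' Reads a CSV/TSV file with a header row, takes the named column as the
#' response, and standardizes the remaining numeric columns.
#'
#' @param file path to a delimited text file.
#' @param response name of the response column.
#' @param sep field separator (default `","`).
#' @return A [regression_data] object.
#' @export
read_regression_csv <- function(file, response, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  if (!response %in% names(df)) stop("response column '", response, "' not found")
  y <- df[[response]]
  Xdf <- df[setdiff(names(df), response)]
  keep <- vapply(Xdf, is.numeric, logical(1))
  if (!all(keep)) Xdf <- Xdf[keep]
  regression_data(as.matrix(Xdf), y)
}

# apply training standardization to new raw rows
standardize_newdata <- function(data, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != data$p) stop("newdata has ", ncol(X_new),
                                  " columns; expected ", data$p)
  sweep(sweep(X_new, 2L, data$x_center), 2L, data$x_scale, "/")
}

# sufficient statistics shared by every model scored on the same data
gram_workspace <- function(data) {
  list(XtX = crossprod(data$X), Xty = drop(crossprod(data$X, data$y)),
       tss = sum(data$y^2), n = data$n, p = data$p)
}

#' OLS summary statistics for one model
#'
#' Fits ordinary least squares on the predictor subset selected by a binary
#' inclusion vector and returns the statistics every Bayes factor needs.
#' Operates on centered/standardized data, so no intercept column appears;
#' the null model (all zeros) has `r2 = 0` by definition.
#'
#' @param data a [regression_data] object.
#' @param gamma binary inclusion vector of length `p`.
#' @return List with `r2`, `ols_coefficients` (named, included variables
#'   only), and `residual_ss`.
#' @examples
#' d <- regression_data(cbind(h = c(62.5, 67.5, 70.5)), c(64.5, 69.5, 72.5))
#' model_fit_stats(d, 1L)$r2  # collinear pair: exactly 1
#' @export
model_fit_stats <- function(data, gamma) {
  gamma <- as.integer(gamma != 0)
  if (length(gamma) != data$p) stop("gamma must have length p")
  d <- sum(gamma)
  if (d > data$n - 2L) stop("saturated model: d > n - 2")
  tss <- sum(data$y^2)
  if (tss <= 0) stop("response has zero variance")
  if (d == 0L)
    return(list(r2 = 0, ols_coefficients = numeric(0), residual_ss = tss))
  sel <- which(gamma == 1L)
  Xs <- data$X[, sel, drop = FALSE]
  qrX <- qr(Xs)
  if (qrX$rank < d) stop("rank-deficient model")
  beta <- qr.coef(qrX, data$y)
  fitted <- drop(Xs %*% beta)
  rss <- sum((data$y - fitted)^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  names(beta) <- data$column_names[sel]
  list(r2 = r2, ols_coefficients = beta, residual_ss = rss)
}
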