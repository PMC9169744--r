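#' Sure independence screening of candidate predictors
#'
#' Reduces a large candidate set to `target_count` variables. One-pass mode
#' ranks by univariate regression \eqn{R^2} (squared marginal correlation on
#' standardized data). Iterative mode (two-round SIS) first takes the top
#' half marginally, fits OLS on the selected block, re-ranks the remaining
#' variables by correlation with the residuals, and tops up to
#' `target_count` — which can recover signals masked by correlated decoys
#' that a single marginal pass misses. Deterministic.
#'
#' @param data a [regression_data] object.
#' @param target_count number of variables to keep (default 30).
#' @param iterative logical; `NULL` (default) uses the iterative refinement
#'   only when `target_count < p / 2`, where one-pass and iterative
#'   screening genuinely differ.
#' @return Integer vector of selected column indices, in selection order;
#'   `1:p` unchanged when `p <= target_count`.
#' @export
screen_variables <- function(data, target_count = 30, iterative = NULL) {
  p <- data$p
  if (p <= target_count) return(seq_len(p))
  uni_r2 <- drop(stats::cor(data$X, data$y))^2
  if (is.null(iterative)) iterative <- target_count < p / 2
  if (!iterative) return(order(uni_r2, decreasing = TRUE)[seq_len(target_count)])
  k1 <- min(ceiling(target_count / 2), p)
  first <- order(uni_r2, decreasing = TRUE)[seq_len(k1)]
  Xs <- data$X[, first, drop = FALSE]
  resid <- stats::lsfit(Xs, data$y, intercept = FALSE)$residuals
  rest <- setdiff(seq_len(p), first)
  res_r2 <- drop(stats::cor(data$X[, rest, drop = FALSE], resid))^2
  second <- rest[order(res_r2, decreasing = TRUE)][seq_len(target_count - k1)]
  c(first, second)
}

# RSS-based branch-and-bound over subsets: best (max R^2) model of each size.
# Bound: R^2 of any subset of F-union-U is at most R^2(F union U).
#' Best subset of each size
#'
#' All-subsets regression: for every model size k the maximal-\eqn{R^2}
#' subset, found by branch and bound with the residual-sum-of-squares bound
#' (any submodel of a candidate set fits no better than the full candidate
#' set). Exhaustive in effect for small p; variables are pre-ordered by
#' univariate \eqn{R^2} to tighten pruning.
#'
#' @param data a [regression_data] object.
#' @param max_p refusal threshold (default 30): above it, screen first with
#'   [screen_variables()].
#' @return List of class `"best_subsets"`: `size` (0..p), `r2` (best
#'   \eqn{R^2} per size), `models` (list of index vectors into the columns
#'   of `data$X`).
#' @export
best_subset_search <- function(data, max_p = 30) {
  p <- data$p
  if (p > max_p)
    stop("p = ", p, " exceeds max_p = ", max_p,
         "; reduce the candidate set with screen_variables()")
  ws <- gram_workspace(data)
  r2_of <- function(sel) {
    if (!length(sel)) return(0)
    A <- ws$XtX[sel, sel, drop = FALSE]
    b <- ws$Xty[sel]
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) return(NA_real_)
    min(max(sum(sol * b) / ws$tss, 0), 1)
  }
  ord <- order(drop(stats::cor(data$X, data$y))^2, decreasing = TRUE)
  best_r2 <- rep(-Inf, p + 1L)
  best_set <- vector("list", p + 1L)
  best_r2[1L] <- 0
  best_set[[1L]] <- integer(0)
  recurse <- function(fixed, undecided, r2_fixed) {
    k <- length(fixed)
    if (!is.na(r2_fixed) && r2_fixed > best_r2[k + 1L]) {
      best_r2[k + 1L] <<- r2_fixed
      best_set[[k + 1L]] <<- fixed
    }
    if (!length(undecided)) return(invisible())
    bound <- r2_of(c(fixed, undecided))
    kmax <- k + length(undecided)
    if (!is.na(bound) &&
        all(bound <= best_r2[(k + 1L):(kmax + 1L)] + 1e-12))
      return(invisible())
    v <- undecided[1L]
    rest <- undecided[-1L]
    recurse(c(fixed, v), rest, r2_of(c(fixed, v)))
    recurse(fixed, rest, r2_fixed)
  }
  recurse(integer(0), ord, 0)
  structure(list(size = 0:p, r2 = best_r2, models = best_set),
            class = "best_subsets")
}

#' Select the data-generating model from a dataset
#'
#' The empirically grounded truth used to seed parametric-bootstrap
#' simulations. Pipeline: for wide candidate sets, screen to at most
#' `screen_target` variables (iterative SIS then top univariate \eqn{R^2});
#' run all-subsets regression; take the largest size whose best model has
#' every coefficient two-sided t-test p-value below `sig_level`; refit OLS
#' on that support. If no size qualifies, fall back to the best
#' single-variable model with a warning.
#'
#' @param data a [regression_data] object.
#' @param sig_level coefficient significance threshold (default 0.05).
#' @param screen_target screening size for wide candidate sets (default 30).
#' @return Object of class `"generating_model"`: `support` (binary length-p
#'   vector), `beta_DG` (length p, zero off support), `alpha_DG` (intercept
#'   on the original response scale), `sigma_DG` (residual SD), `r2_source`.
#' @export
select_generating_model <- function(data, sig_level = 0.05,
                                    screen_target = 30) {
  keep <- if (data$p > screen_target)
    sort(screen_variables(data, screen_target)) else seq_len(data$p)
  sub <- data
  sub$X <- data$X[, keep, drop = FALSE]
  sub$p <- length(keep)
  sub$column_names <- data$column_names[keep]
  subsets <- best_subset_search(sub)
  chosen <- NULL
  for (k in rev(seq_along(subsets$models))) {
    sel <- subsets$models[[k]]
    if (!length(sel) || !is.finite(subsets$r2[k])) next
    fit <- stats::lm(sub$y ~ sub$X[, sel, drop = FALSE])
    pv <- summary(fit)$coefficients[-1L, 4L]
    if (all(pv < sig_level)) {
      chosen <- sel
      break
    }
  }
  if (is.null(chosen)) {
    warning("no model size has all coefficients significant; ",
            "falling back to the best single-variable model")
    chosen <- subsets$models[[2L]]
  }
  sel_global <- keep[chosen]
  fit <- stats::lm(data$y ~ data$X[, sel_global, drop = FALSE])
  beta <- numeric(data$p)
  beta[sel_global] <- stats::coef(fit)[-1L]
  support <- as.integer(seq_len(data$p) %in% sel_global)
  structure(list(support = stats::setNames(support, data$column_names),
                 beta_DG = stats::setNames(beta, data$column_names),
                 alpha_DG = data$y_center,
                 sigma_DG = summary(fit)$sigma,
                 r2_source = summary(fit)$r.squared),
            class = "generating_model")
}

#' @export
#' @method print generating_model
print.generating_model <- function(x, ...) {
  cat(sprintf(
    "generating model: %d of %d variables, sigma = %.4g, source R2 = %.3f\n",
    sum(x$support), length(x$support), x$sigma_DG, x$r2_source))
  invisible(x)
}

#' Serialize a generating model to JSON
#'
#' @param gm a `"generating_model"`.
#' @param file optional output path.
#' @return JSON string (invisibly when written to `file`).
#' @export
generating_model_to_json <- function(gm, file = NULL) {
  obj <- list(support = paste(gm$support, collapse = ""),
              beta_DG = as.numeric(gm$beta_DG), alpha_DG = gm$alpha_DG,
              sigma_DG = gm$sigma_DG, r2_source = gm$r2_source)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Parametric-bootstrap replicate responses
#'
#' Re-simulates responses from a fitted generating model with the design
#' matrix held fixed: \eqn{y^* = \alpha_{DG} + X\beta_{DG} + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma_{DG}^2 I)}, independently per replicate.
#'
#' @param gm a `"generating_model"`.
#' @param X standardized design matrix (n x p, same columns as `beta_DG`).
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed; replicates are deterministic given the seed.
#' @return n x `n_reps` matrix of simulated responses.
#' @export
parametric_bootstrap <- function(gm, X, n_reps = 100, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  X <- as.matrix(X)
  if (ncol(X) != length(gm$beta_DG)) stop("design width mismatch")
  mu <- gm$alpha_DG + drop(X %*% gm$beta_DG)
  set.seed(as.integer(seed))
  mu + matrix(stats::rnorm(nrow(X) * n_reps, 0, gm$sigma_DG), nrow(X), n_reps)
}

#' Random train-test splits
#'
#' Disjoint, exhaustive 75-25 (by default) index partitions, reproducible
#' per seed; the train size rounds up for non-divisible n.
#'
#' @param n number of observations (>= 8).
#' @param fraction train fraction (default 0.75).
#' @param n_splits number of random splits (default 100).
#' @param seed integer seed.
#' @return List of `n_splits` lists, each with integer vectors `train` and
#'   `test`.
#' @export
train_test_split <- function(n, fraction = 0.75, n_splits = 100, seed = 1) {
  if (n < 8) stop("n must be >= 8")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_train <- ceiling(n * fraction)
  set.seed(as.integer(seed))
  lapply(seq_len(n_splits), function(i) {
    tr <- sort(sample.int(n, n_train))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}
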