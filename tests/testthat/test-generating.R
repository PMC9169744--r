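# generating-model pipeline: screening, best subsets, selection, bootstrap

# fixture with a signal masked from marginal screening: x2 has ~zero marginal
# correlation with y yet a strong partial effect (cor(x1, x2) = -0.9)
masked_signal_data <- function(n = 400, p = 40, noise = 0.3, seed = 81) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  x1 <- z1
  x2 <- -0.9 * x1 + sqrt(1 - 0.81) * z2
  rest <- matrix(rnorm(n * (p - 2)), n, p - 2)
  y <- x1 + 0.9 * x2 + rnorm(n, 0, noise)
  regression_data(cbind(x1, x2, rest), y)
}

test_that("screening is the identity for small candidate sets", {
  d <- make_synth_data(100, 10, c(1, rep(0, 9)), seed = 82)
  expect_identical(screen_variables(d, target_count = 30), 1:10)
})

test_that("a dominant predictor ranks first in both screening modes", {
  d <- make_synth_data(300, 50, c(3, rep(0, 49)), seed = 83)
  expect_identical(screen_variables(d, 10, iterative = FALSE)[1], 1L)
  expect_identical(screen_variables(d, 10, iterative = TRUE)[1], 1L)
})

test_that("iterative screening recovers a marginally masked signal", {
  d <- masked_signal_data()
  one_pass <- screen_variables(d, target_count = 6, iterative = FALSE)
  iterated <- screen_variables(d, target_count = 6, iterative = TRUE)
  expect_false(2L %in% one_pass)
  expect_true(2L %in% iterated)
  expect_true(1L %in% iterated)
  # determinism
  expect_identical(iterated, screen_variables(d, 6, iterative = TRUE))
})

test_that("branch-and-bound matches exhaustive best subsets", {
  d <- make_synth_data(120, 10, c(1, -0.8, 0.5, rep(0, 7)), rho = 0.4,
                       seed = 84)
  bb <- best_subset_search(d)
  ws_r2 <- function(sel) model_fit_stats(d, as.integer(1:10 %in% sel))$r2
  for (k in 0:10) {
    best <- if (k == 0) 0 else
      max(combn(10, k, ws_r2))
    expect_equal(bb$r2[k + 1], best, tolerance = 1e-10)
    expect_length(bb$models[[k + 1]], k)
    expect_equal(ws_r2(bb$models[[k + 1]]), bb$r2[k + 1], tolerance = 1e-12)
  }
  expect_identical(sort(bb$models[[11]]), 1:10)  # k = p is the full model
})

test_that("on an orthogonal design the best size-k set is top-k marginal", {
  set.seed(85)
  Q <- scale(qr.Q(qr(matrix(rnorm(200 * 6), 200, 6))))
  y <- drop(Q %*% c(2, 1.5, 1, 0.5, 0, 0)) + rnorm(200, 0, 0.8)
  d <- regression_data(Q, y)
  bb <- best_subset_search(d)
  uni <- order(drop(cor(d$X, d$y))^2, decreasing = TRUE)
  for (k in 1:6)
    expect_setequal(bb$models[[k + 1]], uni[1:k])
})

test_that("the generating model keeps the largest all-significant size", {
  d <- make_synth_data(500, 6, c(2, -1.5, 1, 0, 0, 0), sigma = 1, seed = 421)
  gm <- select_generating_model(d)
  expect_true(all(which(gm$support == 1) >= 1))
  expect_true(all(c(1, 2, 3) %in% which(gm$support == 1)))
  expect_lte(sum(gm$support), 4)
  expect_gt(gm$sigma_DG, 0)
  expect_equal(gm$r2_source,
               summary(lm(d$y ~ d$X[, gm$support == 1]))$r.squared)
  # beta_DG vanishes off support
  expect_true(all(gm$beta_DG[gm$support == 0] == 0))
  # deterministic pipeline
  expect_equal(select_generating_model(d), gm)
})

test_that("pure noise falls back to the single best variable with a warning", {
  d <- make_synth_data(60, 5, rep(0, 5), seed = 87)
  expect_warning(gm <- select_generating_model(d), "falling back")
  expect_equal(sum(gm$support), 1)
})

test_that("the screened pipeline recovers a masked planted support", {
  d <- masked_signal_data(n = 500, p = 40, noise = 0.25, seed = 88)
  gm <- select_generating_model(d, screen_target = 6)
  expect_true(all(c(1, 2) %in% which(gm$support == 1)))
  expect_lte(sum(gm$support), 5)
})

test_that("parametric bootstrap reproduces the generating distribution", {
  d <- make_synth_data(200, 4, c(1, -1, 0, 0), seed = 89)
  gm <- select_generating_model(d)
  # zero noise: every replicate equals the noiseless mean
  gm0 <- gm; gm0$sigma_DG <- 0
  Y0 <- parametric_bootstrap(gm0, d$X, n_reps = 3, seed = 1)
  mu <- gm$alpha_DG + drop(d$X %*% gm$beta_DG)
  expect_equal(Y0[, 1], mu)
  expect_equal(Y0[, 3], mu)
  # CLT: per-observation mean over replicates close to the noiseless mean
  Y <- parametric_bootstrap(gm, d$X, n_reps = 100, seed = 2)
  expect_lt(max(abs(rowMeans(Y) - mu)), 4 * gm$sigma_DG / sqrt(100))
  # OLS refits on replicates are unbiased for beta_DG
  sel <- which(gm$support == 1)
  coefs <- apply(Y, 2, function(yy)
    coef(lm(yy ~ d$X[, sel]))[-1])
  expect_equal(unname(rowMeans(coefs)), unname(gm$beta_DG[sel]),
               tolerance = 4 * gm$sigma_DG / sqrt(100 * 100))
  # determinism
  expect_identical(Y, parametric_bootstrap(gm, d$X, n_reps = 100, seed = 2))
})

test_that("train-test splits are disjoint, exhaustive and reproducible", {
  sp <- train_test_split(100, n_splits = 20, seed = 5)
  expect_length(sp, 20)
  for (s in sp[1:5]) {
    expect_length(s$train, 75)
    expect_length(s$test, 25)
    expect_identical(sort(c(s$train, s$test)), 1:100)
    expect_length(intersect(s$train, s$test), 0)
  }
  expect_identical(sp, train_test_split(100, n_splits = 20, seed = 5))
  # ceil rounding for non-divisible n
  expect_length(train_test_split(10, n_splits = 1, seed = 1)[[1]]$train, 8)
  expect_error(train_test_split(5), "n must be")
})
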