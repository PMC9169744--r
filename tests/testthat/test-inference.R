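# model-averaged estimation and prediction

test_that("a null-dominated posterior yields zero estimates and [0,0] intervals", {
  d <- make_synth_data(300, 2, c(0, 0), seed = 51)
  fit <- bma_lm(d$X, d$y, prior = "g-sqrt-n", method = "enumerate")
  sel <- bms(fit)  # MAP is the null model for pure noise at this n
  expect_equal(unname(map_model(fit$posterior)), c(0L, 0L))
  cs <- bma_coefficients(sel, n_draws = 2000, seed = 1)
  expect_equal(cs$mean, c(0, 0))
  expect_equal(cs$lower, c(0, 0))
  expect_equal(cs$upper, c(0, 0))
  expect_equal(cs$inclusion_prob, c(0, 0))
  # null-model predictions equal the training mean
  pr <- bma_predict(sel, matrix(rnorm(10 * 2), 10, 2), n_draws = 2000, seed = 1)
  expect_equal(pr$point, rep(fit$data$y_center, 10))
})

test_that("a single-model fixed-g posterior shrinks OLS by g/(1+g)", {
  d <- make_synth_data(150, 4, c(1.5, -1, 0, 0), seed = 52)
  fit <- bma_lm(d$X, d$y, prior = "g-sqrt-n", method = "enumerate")
  sel <- bms(fit)
  gam <- map_model(fit$posterior)
  ols <- model_fit_stats(d, gam)$ols_coefficients
  g <- sqrt(d$n)
  expected <- numeric(d$p)
  expected[gam == 1L] <- g / (1 + g) * ols
  expect_equal(unname(coef(sel)), expected, tolerance = 1e-10)
  # Monte Carlo mean agrees with the analytic mean within MC error
  dr <- bmabench:::.posterior_draws(sel$data, sel$posterior, sel$gprior,
                                    20000, seed = 4)
  mc_se <- apply(dr$beta, 2, sd) / sqrt(20000)
  expect_true(all(abs(colMeans(dr$beta) - expected) < 4 * mc_se + 1e-12))
})

test_that("the BMA mean is the mass-weighted mixture of conditional means", {
  d <- make_synth_data(120, 5, c(0.8, 0.5, 0, 0, 0), rho = 0.3, seed = 53)
  fit <- bma_lm(d$X, d$y, prior = "UIP", method = "enumerate")
  post <- fit$posterior
  g <- d$n
  manual <- numeric(d$p)
  for (i in seq_along(post$posterior_mass)) {
    gam <- post$models[i, ]
    if (sum(gam) == 0) next
    ols <- model_fit_stats(d, gam)$ols_coefficients
    manual[gam == 1L] <- manual[gam == 1L] +
      post$posterior_mass[i] * g / (1 + g) * ols
  }
  expect_equal(unname(coef(fit)), manual, tolerance = 1e-9)
})

test_that("credible intervals tighten as the sample grows", {
  widths <- vapply(c(50, 200, 800), function(n) {
    d <- make_synth_data(n, 3, c(1, 0.5, 0), seed = 54)
    fit <- bma_lm(d$X, d$y, prior = "JZS", method = "enumerate")
    cs <- bma_coefficients(fit, n_draws = 4000, seed = 9)
    mean(cs$upper - cs$lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("prediction handles intervals, scale restoration and bad input", {
  set.seed(55)
  Xraw <- matrix(rnorm(200 * 3, 5, 2), 200, 3)
  yraw <- 10 + Xraw[, 1] + rnorm(200)
  fit <- bma_lm(Xraw, yraw, prior = "g-sqrt-n", method = "enumerate")
  newX <- Xraw[1:40, ]
  pr <- bma_predict(fit, newX, n_draws = 4000, seed = 2)
  expect_true(all(pr$lower <= pr$point + 1e-6 & pr$point <= pr$upper + 1e-6))
  # predictions live on the original response scale
  expect_lt(mean(abs(pr$point - yraw[1:40])), 2)
  expect_error(bma_predict(fit, newX[, 1:2], n_draws = 1500, seed = 1),
               "columns")
  expect_warning(bma_coefficients(fit, n_draws = 500, seed = 1),
                 "Monte Carlo")
})

test_that("adaptive-prior draws shrink consistently with their posteriors", {
  d <- make_synth_data(100, 3, c(1.4, 0, 0), seed = 56)
  for (label in c("hyper-g", "JZS", "EB-local")) {
    fit <- bma_lm(d$X, d$y, prior = label, method = "enumerate")
    cs <- bma_coefficients(fit, n_draws = 6000, seed = 3)
    ols <- model_fit_stats(d, c(1L, 0L, 0L))$ols_coefficients
    # posterior mean lies between 0 and OLS (shrinkage), near OLS at n = 100
    expect_gt(cs$mean[1] / ols, 0.8)
    expect_lt(cs$mean[1] / ols, 1.0)
    # interval covers the analytic mean
    expect_true(cs$lower[1] < cs$mean[1] && cs$mean[1] < cs$upper[1])
  }
})

test_that("selection equals averaging when one model holds all the mass", {
  d <- make_synth_data(2000, 2, c(3, 0), sigma = 0.5, seed = 57)
  fit <- bma_lm(d$X, d$y, prior = "UIP", method = "enumerate")
  expect_gt(max(fit$posterior$posterior_mass), 0.9)
  cb <- bma_coefficients(fit, n_draws = 4000, seed = 5)
  cs <- bma_coefficients(bms(fit), n_draws = 4000, seed = 5)
  expect_equal(cb$mean, cs$mean, tolerance = 0.01)
  # on the dominant variable the interval is indistinguishable
  expect_equal(cb$upper[1] - cb$lower[1], cs$upper[1] - cs$lower[1],
               tolerance = 0.05)
})

test_that("bms_infer returns coherent coefficient and prediction summaries", {
  d <- make_synth_data(150, 4, c(2, -1, 0, 0), seed = 58)
  fit <- bma_lm(d$X, d$y, prior = "JZS", method = "enumerate")
  out <- bms_infer(fit, newdata = d$X[1:5, ] , n_draws = 2000, seed = 6)
  expect_s3_class(out$coefficients, "bma_coef")
  expect_length(out$prediction$point, 5)
  gam <- map_model(fit$posterior)
  expect_equal(out$coefficients$inclusion_prob, as.numeric(gam))
})

test_that("draws are reproducible for a fixed seed", {
  d <- make_synth_data(80, 3, c(1, 0, 0), seed = 59)
  fit <- bma_lm(d$X, d$y, prior = "hyper-g", method = "enumerate")
  a <- bma_coefficients(fit, n_draws = 2000, seed = 7)
  b <- bma_coefficients(fit, n_draws = 2000, seed = 7)
  expect_identical(a, b)
})
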