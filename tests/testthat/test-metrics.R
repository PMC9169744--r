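# the five evaluation statistics and model-size accounting

test_that("coefficient RMSE follows the root-mean-square definition", {
  expect_identical(rmse_coefficients(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_coefficients(c(3, 4, 0), c(0, 0, 0)), sqrt(25 / 3))
  # brute-force loop oracle and permutation invariance
  set.seed(71)
  a <- rnorm(10); b <- rnorm(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse_coefficients(a, b), sqrt(acc / 10))
  pp <- sample(10)
  expect_equal(rmse_coefficients(a[pp], b[pp]), rmse_coefficients(a, b))
  expect_error(rmse_coefficients(1:3, 1:4), "length")
})

test_that("the interval score charges width plus 40x exceedance at alpha 0.05", {
  expect_equal(interval_score(0, 2, 1), 2)
  expect_equal(interval_score(0, 1, 1.5), 1 + (2 / 0.05) * 0.5)  # 21
  expect_equal(interval_score(-1, 1, -2), 2 + 40 * 1)            # 42
  expect_error(interval_score(1, 0, 0.5), "exceeds")
  # mean interval score: single pair, all-inside, and the mixed fixture
  expect_equal(mean_interval_score(0, 2, 1), 2)
  expect_equal(mean_interval_score(c(0, -2), c(2, 2), c(1, 0)), 3)
  expect_equal(mean_interval_score(c(0, 0, -1), c(2, 1, 1), c(1, 1.5, -2)),
               (2 + 21 + 42) / 3)
  expect_error(mean_interval_score(numeric(0), numeric(0), numeric(0)),
               "no targets")
  # linearity in the per-pair scores
  l <- c(-1, 0); u <- c(1, 3); z <- c(2, 1)
  expect_equal(mean_interval_score(l, u, z),
               mean(interval_score(l, u, z)))
})

test_that("the interval score is minimized by the nominal-level interval", {
  set.seed(72)
  z <- rnorm(2e5)
  qs <- seq(1.5, 2.5, 0.01)
  risk <- vapply(qs, function(q) mean(interval_score(-q, q, z)), numeric(1))
  expect_lt(abs(qs[which.min(risk)] - qnorm(0.975)), 0.08)
})

test_that("precision-recall areas match the exhaustive-threshold oracle", {
  truth <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.2, 0.8, 0.1)
  # oracle: step-integrated average precision over all distinct thresholds
  oracle <- {
    ths <- sort(unique(scores), decreasing = TRUE)
    rec <- prec <- numeric(0)
    for (t in ths) {
      sel <- scores >= t
      rec <- c(rec, sum(truth[sel]) / sum(truth))
      prec <- c(prec, sum(truth[sel]) / sum(sel))
    }
    ap <- 0; last <- 0
    for (i in seq_along(ths)) if (rec[i] > last) {
      ap <- ap + (rec[i] - last) * prec[i]; last <- rec[i]
    }
    ap
  }
  expect_equal(auprc(truth, scores = scores), oracle)
  expect_equal(oracle, 0.5 * 1 + 0.5 * (2 / 3))
  # perfect ranking and constant scores
  expect_equal(auprc(c(1, 1, 0, 0), scores = c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auprc(truth, scores = rep(0.3, 4)), 0.5)  # prevalence
  expect_error(auprc(c(0, 0), scores = c(1, 2)), "no positives")
  expect_error(auprc(truth, scores = scores, path = diag(4)), "exactly one")
})

test_that("the area is invariant to monotone transforms of the scores", {
  set.seed(73)
  truth <- rbinom(20, 1, 0.4); truth[1] <- 1
  sc <- runif(20)
  a0 <- auprc(truth, scores = sc)
  expect_equal(auprc(truth, scores = exp(3 * sc)), a0)
  expect_equal(auprc(truth, scores = rank(sc)), a0)
})

test_that("path-mode areas use the support sequence along the penalty", {
  truth <- c(1, 1, 0, 0, 0)
  # nested supports: {}, {1}, {1,2}, {1,2,3}
  path <- cbind(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0),
                c(1, 1, 1, 0, 0))
  expect_equal(auprc(truth, path = path), 0.5 * 1 + 0.5 * 1)
  # a path that never recovers variable 2 only reaches recall 1/2
  path2 <- cbind(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(1, 0, 1, 0, 0))
  expect_equal(auprc(truth, path = path2), 0.5 * 1)
})

test_that("test-set R-squared matches its definition and can be negative", {
  set.seed(74)
  y <- rnorm(30, 2)
  expect_equal(r2_test(y, y, 0), 1)
  expect_equal(r2_test(y, rep(1.7, 30), 1.7), 0)
  flip <- -y + 2 * 1.7
  brute <- 1 - sum((y - flip)^2) / sum((y - 1.7)^2)
  expect_equal(r2_test(y, flip, 1.7), brute)
  expect_lt(r2_test(y, flip, 1.7), 0)
  expect_error(r2_test(rep(1, 5), rnorm(5), 1), "constant")
})

test_that("model sizes average inclusion mass or count nonzeros", {
  post <- structure(list(inclusion_prob = c(1, 0.5, 0)),
                    class = "model_posterior")
  expect_equal(average_model_size(post), 1.5)
  null_post <- structure(list(inclusion_prob = c(0, 0, 0)),
                         class = "model_posterior")
  expect_equal(average_model_size(null_post), 0)
  expect_equal(average_model_size(c(0.3, 0, -2)), 2)
  expect_equal(average_model_size(list(post, null_post)), 0.75)
  # expectation identity against enumeration of a 2-model posterior
  d <- make_synth_data(80, 2, c(1, 0), seed = 75)
  pe <- enumerate_posterior(d, gprior("jzs"), model_prior("beta-binomial"))
  manual <- sum(pe$posterior_mass * rowSums(pe$models))
  expect_equal(average_model_size(pe), manual, tolerance = 1e-9)
})
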