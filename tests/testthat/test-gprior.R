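# Bayes factor engine: closed forms, quadrature variants, model-space priors

test_that("g rules resolve as specified", {
  expect_equal(resolve_g(gprior("fixed", g = "sqrt-n"), n = 100), 10)
  expect_equal(resolve_g(gprior("fixed", g = "n"), n = 37), 37)
  expect_equal(resolve_g(gprior("fixed", g = "one"), n = 3116), 1)
  expect_equal(resolve_g(gprior("fixed", g = "benchmark"), n = 50, p = 10), 100)
  expect_equal(resolve_g(gprior("fixed", g = "benchmark"), n = 500, p = 10), 500)
  expect_equal(resolve_g(gprior("fixed", g = 7.5), n = 10), 7.5)
  expect_error(gprior("fixed", g = "half-n"), "unknown g rule")
  expect_error(gprior("fixed", g = -2), "positive")
})

test_that("fixed-g log Bayes factor matches the exact -2 log B identity", {
  set.seed(101)
  for (i in 1:200) {
    r2 <- runif(1)
    n <- sample(5:5000, 1)
    d <- sample.int(min(n - 3, 40), 1)
    g <- exp(runif(1, -2, 8))
    minus2 <- (n - 1) * log(1 + g * (1 - r2)) - (n - 1 - d) * log(1 + g)
    expect_equal(-2 * log_bf_fixed_g(r2, n, d, g), minus2, tolerance = 1e-10)
  }
})

test_that("the three-height worked example gives Bayes factor 1.65", {
  d <- father_son_data()
  fs <- model_fit_stats(d, 1L)
  expect_identical(fs$r2, 1)
  bf <- exp(log_bf_fixed_g(fs$r2, n = 3, d = 1, g = sqrt(3)))
  expect_equal(round(bf, 2), 1.65)
  # closed form vs direct numerical integration of the marginals
  bf_int <- .bf_by_integration(d$X, d$y, g = sqrt(3))
  expect_equal(bf, bf_int, tolerance = 1e-6)
  # and at g = 3: BF = (1 + 3)^{1/2} = 2
  expect_equal(exp(log_bf_fixed_g(1, 3, 1, 3)), 2, tolerance = 1e-12)
  expect_equal(.bf_by_integration(d$X, d$y, g = 3), 2, tolerance = 1e-6)
  # unit-information prior (g = n) on a noisy small dataset
  set.seed(7)
  X <- matrix(rnorm(6), ncol = 1)
  y <- drop(X) * 0.8 + rnorm(6, 0, 0.7)
  dd <- regression_data(X, y)
  r2 <- model_fit_stats(dd, 1L)$r2
  expect_equal(exp(log_bf_fixed_g(r2, 6, 1, 6)),
               .bf_by_integration(dd$X, dd$y, g = 6), tolerance = 1e-6)
})

test_that("fixed-g Bayes factors have a finite ceiling, huge already at n = 20", {
  expect_gt(exp(max_log_bf_fixed_g(20, 1, sqrt(20))), 4e6)
  expect_equal(max_log_bf_fixed_g(3, 1, sqrt(3)), log_bf_fixed_g(1, 3, 1, sqrt(3)))
  expect_equal(max_log_bf_fixed_g(10, 0, sqrt(10)), 0)
  ns <- c(10, 50, 200, 1000, 5000)
  ceilings <- vapply(ns, function(n) max_log_bf_fixed_g(n, 1, sqrt(n)),
                     numeric(1))
  expect_true(all(diff(ceilings) > 0))
})

test_that("hyper-g matches the hypergeometric series and the mixing integral", {
  # direct 2F1((n-1)/2, 1; (d+a)/2; r2) power series at moderate n
  series_2f1 <- function(A, C, z, iter = 50000) {
    lt <- 0; s <- 1
    for (k in seq_len(iter)) {
      lt <- lt + log((A + k - 1) * z / (C + k - 1))
      s <- s + exp(lt)
      if (exp(lt) < 1e-16 * s && k > 10) break
    }
    s
  }
  for (cs in list(c(r2 = 0.5, n = 50, d = 3, a = 3),
                  c(r2 = 0.2, n = 30, d = 2, a = 2.5),
                  c(r2 = 0.8, n = 80, d = 5, a = 4))) {
    oracle <- log((cs["a"] - 2) / (cs["d"] + cs["a"] - 2) *
                    series_2f1((cs["n"] - 1) / 2, (cs["d"] + cs["a"]) / 2,
                               cs["r2"]))
    expect_equal(log_bf_hyper_g(cs["r2"], cs["n"], cs["d"], cs["a"]),
                 unname(oracle), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
  # Monte Carlo mixture of the fixed-g BF over pi(g) = (a-2)/2 (1+g)^{-a/2}
  set.seed(11)
  u <- runif(5e5)
  g <- (1 - u)^(-2 / (3 - 2)) - 1  # inverse CDF for a = 3
  lb <- log_bf_fixed_g(0.5, 50, 3, g)
  m <- max(lb)
  expect_equal(log_bf_hyper_g(0.5, 50, 3, 3), m + log(mean(exp(lb - m))),
               tolerance = 0.01)
})

test_that("hyper-g diverges at a perfect fit; fixed-g does not", {
  expect_identical(log_bf_hyper_g(1, 3, 1, 3), Inf)
  expect_identical(log_bf_eb_local(1, 3, 1), Inf)
  expect_true(is.finite(log_bf_fixed_g(1, 3, 1, sqrt(3))))
  expect_true(is.finite(log_bf_fixed_g(1, 1000, 10, 1000)))
  # non-divergent corner: d + a > n + 1 has the finite limit (a-2)/(d+a-n-1)
  expect_equal(log_bf_hyper_g(1, 3, 1, 4), log(2), tolerance = 1e-12)
})

test_that("local empirical Bayes equals the g-maximized fixed-g evidence", {
  grid <- exp(seq(log(1e-8), log(1e8), length.out = 40000))
  for (cs in list(c(0.5, 50, 3), c(0.9, 200, 5), c(0.1, 30, 2))) {
    oracle <- max(log_bf_fixed_g(cs[1], cs[2], cs[3], grid), 0)
    expect_equal(log_bf_eb_local(cs[1], cs[2], cs[3]), oracle,
                 tolerance = 1e-6)
  }
  # F <= 1 clips ghat to zero
  expect_identical(log_bf_eb_local(0.01, 50, 5), 0)
  expect_error(log_bf_eb_local(0.5, 5, 4), "saturated")
})

test_that("JZS quadrature agrees with Monte Carlo and Laplace oracles", {
  # g ~ inverse-gamma(1/2, n/2) Monte Carlo average of the fixed-g BF
  set.seed(3)
  n <- 50
  g <- (n / 2) / rgamma(1e6, 0.5)
  lb <- log_bf_fixed_g(0.5, n, 3, g)
  m <- max(lb)
  mc <- m + log(mean(exp(lb - m)))
  se <- sd(exp(lb - m)) / sqrt(1e6) / mean(exp(lb - m))
  expect_equal(log_bf_jzs(0.5, n, 3), mc, tolerance = max(3 * se, 1e-3))
  # Laplace approximation on the log-g scale at larger n
  laplace <- function(r2, n, d) {
    h <- function(t) {
      g <- exp(t)
      0.5 * log(n / 2) - lgamma(0.5) - 1.5 * t - n / (2 * g) +
        ((n - 1 - d) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - r2)) + t
    }
    opt <- stats::optimize(h, c(-10, 25), maximum = TRUE, tol = 1e-12)
    s <- 1e-4
    d2 <- (h(opt$maximum + s) - 2 * opt$objective + h(opt$maximum - s)) / s^2
    opt$objective + 0.5 * log(2 * pi) - 0.5 * log(-d2)
  }
  lj <- log_bf_jzs(0.9, 200, 5)
  expect_equal(lj, laplace(0.9, 200, 5), tolerance = 0.005 * abs(lj))
  expect_identical(log_bf_jzs(0.4, 100, 0), 0)
})

test_that("information-criterion weights reproduce BIC/AIC differences", {
  expect_identical(log_weight_ic("bic", 0, 100, 0), 0)
  expect_equal(log_weight_ic("bic", 0.5, 100, 2),
               -(100 * log(0.5) + 2 * log(100)) / 2)
  set.seed(21)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- X[, 1] + rnorm(120)
  d <- regression_data(X, y)
  f0 <- lm(d$y ~ 1)
  f1 <- lm(d$y ~ d$X[, 1:2])
  r2 <- model_fit_stats(d, c(1L, 1L, 0L))$r2
  expect_equal(-2 * (log_weight_ic("bic", r2, 120, 2) -
                       log_weight_ic("bic", 0, 120, 0)),
               BIC(f1) - BIC(f0), tolerance = 1e-8)
  expect_equal(-2 * (log_weight_ic("aic", r2, 120, 2) -
                       log_weight_ic("aic", 0, 120, 0)),
               AIC(f1) - AIC(f0), tolerance = 1e-8)
})

test_that("the sqrt-n prior's complexity penalty is about half of BIC's", {
  n <- exp(seq(log(100), log(1e5), length.out = 50))
  pen_exact <- log(1 + sqrt(n))       # per-variable penalty in the exact form
  pen_half_bic <- log(n) / 2
  expect_true(all(abs(pen_exact / pen_half_bic - 1) < 0.10))
})

test_that("Bartlett's paradox: evidence collapses as g grows without bound", {
  lb <- log_bf_fixed_g(0.6, 100, 3, 10^seq(2, 40, 2))
  expect_true(all(diff(lb) < 0))
  expect_lt(lb[20], -50)
})

test_that("adding an uninformative variable lowers every Bayes factor", {
  r2 <- 0.55; n <- 120
  for (d in 1:6) {
    expect_lt(log_bf_fixed_g(r2, n, d + 1, sqrt(n)),
              log_bf_fixed_g(r2, n, d, sqrt(n)))
    expect_lt(log_bf_hyper_g(r2, n, d + 1), log_bf_hyper_g(r2, n, d))
    expect_lt(log_bf_jzs(r2, n, d + 1), log_bf_jzs(r2, n, d))
    expect_lt(log_weight_ic("bic", r2, n, d + 1),
              log_weight_ic("bic", r2, n, d))
    expect_lt(log_weight_ic("aic", r2, n, d + 1),
              log_weight_ic("aic", r2, n, d))
  }
})

test_that("every variant anchors the null model at zero", {
  specs <- list(gprior("fixed", g = "sqrt-n"), gprior("fixed", g = "n"),
                gprior("hyper-g"), gprior("eb-local"), gprior("jzs"),
                gprior("bic"), gprior("aic"))
  for (s in specs) expect_identical(log_marginal(s, 0, 50, 0, p = 5), 0)
})

test_that("model-space priors normalize and truncate as specified", {
  mp <- model_prior("beta-binomial")
  # p = 2: the four models carry masses 1/3, 1/6, 1/6, 1/3
  masses <- exp(model_log_prior(mp, d = c(0, 1, 1, 2), p = 2))
  expect_equal(masses, c(1/3, 1/6, 1/6, 1/3))
  expect_equal(sum(masses), 1)
  # enumeration oracle at p = 5: sizes weighted by binomial counts sum to 1
  expect_equal(sum(choose(5, 0:5) * exp(model_log_prior(mp, 0:5, p = 5))), 1)
  expect_equal(model_log_prior(model_prior("uniform"), d = 2, p = 3),
               log(1 / 8))
  tr <- model_prior("truncated")
  expect_identical(model_log_prior(tr, d = 9, p = 120, n = 10), -Inf)
  # truncated masses renormalize over admissible sizes
  lp <- model_log_prior(tr, 0:120, p = 120, n = 10)
  expect_equal(sum(choose(120, 0:120) * exp(lp)), 1)
})

test_that("C++ model scorer agrees with the reference R marginals", {
  set.seed(31)
  d <- make_synth_data(150, 8, c(1, -0.7, rep(0, 6)), rho = 0.4, seed = 31)
  for (label in c("g-sqrt-n", "UIP", "hyper-g", "EB-local", "JZS", "BIC",
                  "AIC")) {
    gs <- gprior_method(label)
    post <- enumerate_posterior(d, gs, model_prior("beta-binomial"))
    idx <- order(post$posterior_mass, decreasing = TRUE)[1:10]
    ref <- mapply(function(r2, dd) log_marginal(gs, r2, d$n, dd, p = d$p),
                  post$r2[idx], post$d[idx])
    expect_equal(post$log_marginal[idx], unname(ref), tolerance = 1e-7)
  }
})
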