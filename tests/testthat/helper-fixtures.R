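# shared fixtures built in code; no data files

father_son_data <- function() {
  regression_data(cbind(height = c(62.5, 67.5, 70.5)), c(64.5, 69.5, 72.5))
}

# small correlated regression dataset with known sparse truth
make_synth_data <- function(n, p, beta, sigma = 1, rho = 0, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z
  if (rho != 0 && p > 1)
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  regression_data(X, y)
}

# total-variation distance between two model posteriors over the model space
tv_distance <- function(postA, postB) {
  kA <- apply(postA$models, 1, paste, collapse = "")
  kB <- apply(postB$models, 1, paste, collapse = "")
  keys <- union(kA, kB)
  mA <- stats::setNames(numeric(length(keys)), keys)
  mB <- mA
  mA[kA] <- postA$posterior_mass
  mB[kB] <- postB$posterior_mass
  0.5 * sum(abs(mA - mB))
}

# independent oracle: marginal likelihood of the raw (uncentered) regression
# by generic Gaussian linear algebra over (alpha, beta) -- determinants and
# quadratic forms, never the R^2 shortcut -- and numerical integration over
# log sigma. pi(alpha, sigma) proportional to 1/sigma throughout.
.bf_by_integration <- function(X, y, g) {
  n <- length(y)
  X <- as.matrix(X)
  log_m_sigma <- function(lsig, with_beta) {
    sig <- exp(lsig)
    W <- if (with_beta) cbind(1, X) else matrix(1, n, 1)
    k <- ncol(W)
    d <- k - 1L
    G <- if (d > 0) crossprod(X) else matrix(0, 0, 0)
    P <- matrix(0, k, k)
    if (d > 0) P[-1L, -1L] <- G / g
    A <- crossprod(W) + P
    b <- drop(crossprod(W, y))
    quad <- sum(y^2) - drop(crossprod(b, solve(A, b)))
    -n / 2 * log(2 * pi * sig^2) + k / 2 * log(2 * pi * sig^2) -
      0.5 * determinant(A)$modulus +
      (if (d > 0) -d / 2 * log(2 * pi * sig^2 * g) +
         0.5 * determinant(G)$modulus else 0) -
      quad / (2 * sig^2)
  }
  log_marg <- function(with_beta) {
    grid <- seq(-15, 12, length.out = 400)
    M <- max(vapply(grid, log_m_sigma, numeric(1), with_beta = with_beta))
    val <- stats::integrate(function(t) vapply(t, function(tt)
      exp(log_m_sigma(tt, with_beta) - M), numeric(1)),
      -15, 12, rel.tol = 1e-12, subdivisions = 1000L)$value
    M + log(val)
  }
  exp(log_marg(TRUE) - log_marg(FALSE))
}

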