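# Fixed small datasets and independent brute-force oracles used across the
# suite.  Oracles deliberately use naive linear algebra (explicit inversion,
# literal two-stage regression, grid search) so they share no code path with
# the package implementation.

# 8-row, 2-column fixed design for the OLS normal-equations oracle.
fixture_ols8 <- function() {
  X <- cbind(x1 = c(1.0, 2.0, 0.5, -1.0, 3.0, -2.0, 0.0, 1.5),
             x2 = c(0.5, -1.0, 2.0, 1.0, 0.0, 1.5, -0.5, 2.5))
  y <- c(1.2, 0.7, 2.9, 0.8, 2.1, 0.3, -0.4, 4.0)
  list(y = y, X = X)
}

# 12-row fixed dataset: one endogenous column, two instruments, intercept.
fixture_iv12 <- function() {
  z1 <- c(0.3, -1.2, 0.8, 1.5, -0.7, 0.1, 2.0, -1.8, 0.9, -0.3, 1.1, 0.6)
  z2 <- c(1.0, 0.4, -0.9, 0.2, 1.3, -1.1, 0.5, 0.8, -1.5, 0.7, -0.2, 1.9)
  u <- c(0.5, -0.2, 0.9, -1.1, 0.3, 0.8, -0.6, 0.1, 1.2, -0.9, 0.4, -0.5)
  x <- 0.8 * z1 - 0.5 * z2 + u +
    c(0.1, -0.3, 0.2, 0.4, -0.1, 0.0, 0.3, -0.2, 0.1, 0.2, -0.4, 0.1)
  y <- 1.5 + 0.7 * x - 1.2 * u +
    c(0.2, 0.1, -0.2, 0.3, 0.0, -0.1, 0.2, -0.3, 0.1, 0.0, 0.2, -0.1)
  list(y = y,
       X1 = cbind(x = x),
       X2 = cbind(const = rep(1, 12)),
       Z1 = cbind(z1 = z1, z2 = z2))
}

# Well-conditioned random instrumental-variable data with genuine
# endogeneity (shared confounder between the dose and the outcome error).
random_iv_data <- function(n = 80, l1 = 3, seed = 1) {
  set.seed(seed)
  conf <- rnorm(n)
  Z1 <- matrix(rnorm(n * l1), n, l1,
               dimnames = list(NULL, paste0("z", seq_len(l1))))
  x <- drop(Z1 %*% runif(l1, 0.4, 1)) + conf + rnorm(n)
  b <- rnorm(n)
  y <- 0.5 * x + 0.3 * b + 1 + conf + rnorm(n)
  regression_data(y, X1 = cbind(x = x),
                  X2 = cbind(b = b, const = 1), Z1 = Z1)
}

# Explicit-inversion OLS oracle.
ols_oracle <- function(y, X) unname(drop(solve(t(X) %*% X) %*% t(X) %*% y))

# Literal two-stage oracle: first stage by lm per endogenous column, then
# second-stage lm on the predicted design.
two_stage_oracle <- function(y, X1, X2, Z1) {
  Z <- cbind(Z1, X2)
  X1hat <- apply(X1, 2, function(x) fitted(stats::lm.fit(Z, x)))
  Xhat <- cbind(X1hat, X2)
  unname(drop(solve(t(Xhat) %*% Xhat) %*% t(Xhat) %*% y))
}

# Classical exactly-identified IV oracle.
iv_closed_form_oracle <- function(y, X, Z)
  unname(drop(solve(t(Z) %*% X) %*% t(Z) %*% y))

# Nested-model partial-F oracle from two independent regressions.
partial_f_oracle <- function(x, X2, Z, l1) {
  rss1 <- sum(residuals(stats::lm.fit(Z, x))^2)
  rss0 <- if (ncol(X2)) sum(residuals(stats::lm.fit(X2, x))^2) else sum(x^2)
  n <- length(x)
  ((rss0 - rss1) / l1) / (rss1 / (n - ncol(Z)))
}

# Grid-search argmin of the combined trace MSE over alpha in [-2, 3].
grid_alpha_oracle <- function(mse_tsls, mse_ols, cse, step = 1e-4) {
  a <- seq(-2, 3, by = step)
  A <- sum(diag(mse_tsls)); B <- sum(diag(mse_ols)); C <- sum(diag(cse))
  g <- a^2 * A + 2 * a * (1 - a) * C + (1 - a)^2 * B
  a[which.min(g)]
}

# Random symmetric positive semi-definite matrix.
random_psd <- function(k) {
  m <- matrix(rnorm(k * k), k)
  crossprod(m) / k
}

# Hand-built estimator fit for shrinkage arithmetic tests.
manual_fit <- function(method, coefficients, covariance, xtx_inv = NULL,
                       sigma2 = 1, dof = 10) {
  spslreg:::new_estimator_fit(method, coefficients, covariance, sigma2, dof,
                              xtx_inv)
}
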