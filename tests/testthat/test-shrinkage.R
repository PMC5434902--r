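test_that("the cross-squared-error plug-in is the analytic covariance of the pair", {
  d <- random_iv_data(n = 100, seed = 21)
  ols <- fit_ols(d); tsls <- fit_tsls(d)
  cse <- estimate_cse(ols, tsls, d)
  expect_equal(cse, t(cse))
  expect_gte(min(eigen(cse, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # the projection identity X'Xhat = Xhat'Xhat underpinning the plug-in
  Xhat <- qr.fitted(qr(d$Z), d$X)
  expect_equal(t(d$X) %*% Xhat, t(Xhat) %*% Xhat, tolerance = 1e-8)
  # with Z = X the estimators coincide and the CSE equals the OLS
  # covariance up to which residual-variance estimate is plugged in
  self <- regression_data(d$y, X1 = d$X1, X2 = d$X2,
                          Z1 = `colnames<-`(d$X1, "xz"))
  o2 <- fit_ols(self); t2 <- fit_tsls(self)
  expect_equal(estimate_cse(o2, t2, self) / t2$sigma2,
               vcov(o2) / o2$sigma2, tolerance = 1e-8)
})

test_that("cross-squared-error plug-in matches the Monte Carlo cross-moment", {
  # exogenous-dose scenario so both estimators are unbiased and the cross
  # moment is a pure covariance
  solved <- solve_scenario(scenario(eta = 0, kappa = 0.5, n = 1000))
  truth <- c(solved$beta_S, solved$beta_B)
  m <- 3000
  seeds <- spslreg:::spawn_seeds(97L, m)
  cross <- matrix(0, 2, 2); plug <- matrix(0, 2, 2)
  dev_sq <- numeric(m)
  for (t in seq_len(m)) {
    tr <- simulate_trial(solved, seeds[t])
    rd <- spslreg:::fast_rd(tr$Y, cbind(S = tr$S), cbind(B = tr$B),
                            cbind(R = tr$R, RB = tr$R * tr$B))
    o <- fit_ols(rd); ts <- fit_tsls(rd)
    cm <- tcrossprod(coef(ts) - truth, coef(o) - truth)
    cross <- cross + cm / m
    plug <- plug + solved$sigma_eps2 * (o$xtx_inv) / m
    dev_sq[t] <- cm[1, 1]
  }
  # Monte Carlo error of the leading element governs the tolerance
  mc_se <- stats::sd(dev_sq) / sqrt(m)
  expect_lt(max(abs(cross - plug)), 6 * mc_se)
})

test_that("theoretical alpha is the argmin of the combined trace MSE", {
  M <- random_psd(3) + diag(3)
  C <- 0.3 * random_psd(3)
  expect_equal(theoretical_alpha(M, M, C), 0.5)           # symmetric risks
  # convexity: second differences of the criterion are nonnegative and the
  # closed form agrees with a fine grid search
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    A <- random_psd(k); B <- random_psd(k); C2 <- 0.5 * random_psd(k)
    den <- sum(diag(A)) - 2 * sum(diag(C2)) + sum(diag(B))
    if (den < 0.2) next      # keep the argmin well inside the search grid
    a_grid <- seq(-2, 3, by = 1e-3)
    g <- a_grid^2 * sum(diag(A)) + 2 * a_grid * (1 - a_grid) * sum(diag(C2)) +
      (1 - a_grid)^2 * sum(diag(B))
    expect_gte(min(diff(diff(g))), -1e-12)
    expect_lt(abs(theoretical_alpha(A, B, C2) - grid_alpha_oracle(A, B, C2)),
              2e-3)
  }
  # flat criterion is refused
  expect_error(theoretical_alpha(diag(2), diag(2), diag(2)),
               class = "spslreg_degenerate_shrinkage_error")
})

test_that("empirical shrinkage weight follows the positive-part Stein rule", {
  xtx_inv <- diag(2) * 0.1
  ols <- manual_fit("OLS", c(1, 1), 0.1 * diag(2), xtx_inv = xtx_inv,
                    sigma2 = 1)
  tsls <- manual_fit("TSLS", c(2, 0), 0.4 * diag(2), xtx_inv = xtx_inv,
                     sigma2 = 1.2)
  cse <- 0.1 * diag(2)
  d <- alpha_hat(ols, tsls, cse)
  # hand arithmetic: tau = tr(0.4 I - 0.1 I) = 0.6; dist^2 = 1 + 1 = 2
  expect_equal(d$tau_hat, 0.6)
  expect_equal(d$dist_sq, 2)
  expect_equal(d$stein_factor, 0.3)
  expect_equal(d$alpha_hat, 0.7)
  expect_equal(d$stein_factor * d$dist_sq, d$tau_hat, tolerance = 1e-10)

  # zero variance excess: nothing to shrink, pure TSLS
  d2 <- alpha_hat(ols, manual_fit("TSLS", c(2, 0), 0.1 * diag(2),
                                  xtx_inv = xtx_inv), cse)
  expect_equal(d2$alpha_hat, 1)
  # excess larger than the squared distance: truncated at OLS
  d3 <- alpha_hat(ols, manual_fit("TSLS", c(1.01, 1), 0.9 * diag(2),
                                  xtx_inv = xtx_inv), cse)
  expect_equal(d3$alpha_hat, 0)
})

test_that("coincident OLS and TSLS fits raise the degenerate flag", {
  d <- random_iv_data(n = 60, seed = 23)
  self <- regression_data(d$y, X1 = d$X1, X2 = d$X2,
                          Z1 = `colnames<-`(d$X1, "xz"))
  fit <- fit_spsl(self)
  expect_true(fit$diagnostics$degenerate)
  expect_equal(fit$diagnostics$alpha_hat, 0)
  expect_equal(coef(fit), coef(fit$diagnostics$ols_fit), tolerance = 1e-10)
  expect_equal(coef(fit), coef(fit$diagnostics$tsls_fit), tolerance = 1e-10)
})

test_that("SPSL is the affine combination of OLS and TSLS", {
  d <- random_iv_data(n = 90, seed = 25)
  at1 <- fit_spsl(d, alpha = 1)
  expect_equal(coef(at1), coef(fit_tsls(d)), tolerance = 1e-12)
  at0 <- fit_spsl(d, alpha = 0)
  expect_equal(coef(at0), coef(fit_ols(d)), tolerance = 1e-12)

  fit <- fit_spsl(d)
  dg <- fit$diagnostics
  b_ols <- coef(dg$ols_fit); b_tsls <- coef(dg$tsls_fit)
  expect_equal(coef(fit),
               dg$alpha_hat * b_tsls + (1 - dg$alpha_hat) * b_ols,
               tolerance = 1e-12)
  # collinearity: the combination lies on the line through the two fits
  v1 <- coef(fit) - b_ols; v2 <- b_tsls - b_ols
  cr <- v1[1] * v2[2] - v1[2] * v2[1]
  expect_lt(abs(cr), 1e-10 * sqrt(sum(v2^2)))
  # reported covariance is the plug-in combination at alpha_hat
  a <- fit$alpha
  expect_equal(vcov(fit),
               a^2 * vcov(dg$tsls_fit) + 2 * a * (1 - a) * dg$cse +
                 (1 - a)^2 * vcov(dg$ols_fit),
               tolerance = 1e-12)
})

test_that("pairs-bootstrap standard errors behave as expected", {
  # noiseless data: every resampled fit recovers the same coefficients
  set.seed(33)
  X1 <- cbind(a = rnorm(40)); X2 <- cbind(const = rep(1, 40))
  y <- drop(cbind(X1, X2) %*% c(2, -1))
  d0 <- regression_data(y, X1, X2, Z1 = cbind(z = X1[, 1] + 0.001 * rnorm(40)))
  se0 <- bootstrap_se(d0, "OLS", B = 50, seed = 3)
  expect_lt(max(se0), 1e-10)

  # reproducibility under the same seed
  d <- random_iv_data(n = 80, seed = 27)
  s1 <- bootstrap_se(d, "SPSL", B = 60, seed = 9)
  s2 <- bootstrap_se(d, "SPSL", B = 60, seed = 9)
  expect_identical(as.numeric(s1), as.numeric(s2))

  # at large n the OLS bootstrap approaches the analytic standard errors
  big <- random_iv_data(n = 5000, seed = 29)
  sb <- bootstrap_se(big, "OLS", B = 300, seed = 11)
  analytic <- sqrt(diag(vcov(fit_ols(big))))
  expect_lt(max(abs(sb - analytic) / analytic), 0.10)
})
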