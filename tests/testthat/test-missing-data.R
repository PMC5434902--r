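make_complete_trial <- function(n = 300, seed = 101, eta = 0, kappa = 0.5) {
  d <- simulate_trial(solve_scenario(scenario(eta = eta, kappa = kappa, n = n)),
                      seed = seed)
  d$U <- NULL                      # the confounder is never observed
  as.data.frame(d)
}

trial_roles <- list(outcome = "Y", endogenous = "S", exogenous = "B",
                    instruments = c("R", "RB"))

with_product <- function(df) transform(df, RB = R * B)

test_that("MAR amputation follows the logistic missingness model", {
  d <- make_complete_trial()
  # all slopes zero with a hugely negative intercept: nothing removed
  none <- ampute_mar(d, list(list(target = "Y", intercept = -50,
                                  slopes = c(B = 0))), seed = 1)
  expect_false(anyNA(none))
  # certain missingness in a whole column violates the table invariants
  expect_error(ampute_mar(d, list(list(target = "Y", intercept = 50,
                                       slopes = c(B = 0))), seed = 1),
               class = "spslreg_contract_error")
  # missingness may not depend on a column that is itself amputed
  expect_error(ampute_mar(d, list(list(target = "Y", intercept = 0,
                                       slopes = c(S = 1)),
                                  list(target = "S", intercept = -2,
                                       slopes = c(B = 0))), seed = 1),
               class = "spslreg_contract_error")

  # positive slope on B: missingness in Y concentrates at high B
  big <- make_complete_trial(n = 10000, seed = 5)
  inc <- ampute_mar(big, list(list(target = "Y", intercept = -1,
                                   slopes = c(B = 2))), seed = 7)
  q <- quantile(big$B, c(0.25, 0.75))
  rate_hi <- mean(is.na(inc$Y[big$B >= q[2]]))
  rate_lo <- mean(is.na(inc$Y[big$B <= q[1]]))
  expect_gt(rate_hi, rate_lo)
  # same seed reproduces the same mask
  inc2 <- ampute_mar(big, list(list(target = "Y", intercept = -1,
                                    slopes = c(B = 2))), seed = 7)
  expect_identical(attr(inc, "mask"), attr(inc2, "mask"))
})

test_that("chained-equations imputation handles the degenerate cases exactly", {
  d <- make_complete_trial(n = 80)
  # complete input: all copies identical to it
  copies <- impute_chained(d, I = 3, sweeps = 2, seed = 2)
  expect_length(copies, 3)
  for (cp in copies) expect_equal(cp, d)

  # a single missing cell in a column that is an exact linear function of
  # the others is restored deterministically in every copy
  d2 <- d[, c("Y", "S", "B")]
  d2$L <- 2 * d2$S - d2$B + 1
  truth <- d2$L[11]
  d2$L[11] <- NA
  copies2 <- impute_chained(d2, I = 4, sweeps = 3, seed = 3)
  for (cp in copies2) expect_equal(cp$L[11], truth, tolerance = 1e-6)
})

test_that("imputation is seed-reproducible and seed-sensitive but stable", {
  d <- make_complete_trial(n = 500, seed = 41)
  inc <- ampute_mar(d, list(list(target = "Y", intercept = -0.8,
                                 slopes = c(B = 1))), seed = 11)
  i1 <- impute_chained(inc, I = 5, sweeps = 5, seed = 21)
  i2 <- impute_chained(inc, I = 5, sweeps = 5, seed = 21)
  expect_identical(i1[[2]], i2[[2]])
  i3 <- impute_chained(inc, I = 5, sweeps = 5, seed = 22)
  expect_false(identical(i1[[1]]$Y, i3[[1]]$Y))

  # pooled estimates from different imputation seeds agree within pooled SEs
  fit_pool <- function(copies) {
    pool_rubin(lapply(copies, function(cp)
      fit_ols(spslreg:::roles_to_data(with_product(cp), trial_roles))))
  }
  p1 <- fit_pool(lapply(i1, identity))
  p3 <- fit_pool(lapply(i3, identity))
  expect_lt(abs(p1$coefficients["S"] - p3$coefficients["S"]),
            3 * p1$se["S"])
})

test_that("imputed-data estimates track the full-data benchmark", {
  d <- make_complete_trial(n = 500, seed = 61)
  full <- fit_ols(spslreg:::roles_to_data(with_product(d), trial_roles))
  inc <- ampute_mar(d, list(list(target = "Y", intercept = -0.9,
                                 slopes = c(B = 1))), seed = 13)
  expect_gt(attr(inc, "missing_rate")[["Y"]], 0.15)
  copies <- impute_chained(inc, I = 50, sweeps = 5, seed = 15)
  pooled <- pool_rubin(lapply(copies, function(cp)
    fit_ols(spslreg:::roles_to_data(with_product(cp), trial_roles))))
  expect_lt(abs(pooled$coefficients["S"] - coef(full)["S"]),
            3 * pooled$se["S"])
})

test_that("Rubin's rules pool estimates and variances correctly", {
  # hand-computed two-imputation example
  fits <- list(list(coefficients = c(b = 1), variance = c(b = 1)),
               list(coefficients = c(b = 3), variance = c(b = 1)))
  p <- pool_rubin(fits)
  expect_equal(unname(p$coefficients), 2)
  expect_equal(unname(p$between), 2)           # (1-2)^2 + (3-2)^2 over I-1
  expect_equal(unname(p$se), 2)                # sqrt(1 + 3/2 * 2)

  # identical fits: between-variance collapses to zero
  same <- replicate(4, list(coefficients = c(a = 1.5, b = -2),
                            variance = c(a = 0.3, b = 0.6)),
                    simplify = FALSE)
  ps <- pool_rubin(same)
  expect_equal(unname(ps$between), c(0, 0))
  expect_equal(ps$se, sqrt(ps$within))

  # permutation invariance and the within-variance lower bound
  set.seed(71)
  fits2 <- lapply(1:6, function(i)
    list(coefficients = c(a = rnorm(1), b = rnorm(1)),
         variance = c(a = runif(1), b = runif(1))))
  pa <- pool_rubin(fits2)
  pb <- pool_rubin(fits2[sample(6)])
  expect_equal(pa$coefficients, pb$coefficients)
  expect_equal(pa$se, pb$se)
  expect_true(all(pa$se >= sqrt(pa$within)))

  # inconsistent coefficient sets are refused
  expect_error(pool_rubin(list(list(coefficients = c(a = 1), variance = 1),
                               list(coefficients = c(b = 1), variance = 1))),
               class = "spslreg_contract_error")
})

test_that("the impute-and-fit workflow pools all three estimators", {
  d <- with_product(make_complete_trial(n = 250, seed = 81, eta = 0.25))
  inc <- ampute_mar(d, list(list(target = "Y", intercept = -1.2,
                                 slopes = c(B = 0.8))), seed = 17)
  out <- impute_fit(inc, trial_roles, I = 4, sweeps = 3,
                    seed = 19, B = 40)
  expect_named(out, c("OLS", "TSLS", "SPSL"))
  for (p in out) {
    expect_s3_class(p, "pooled_fit")
    expect_equal(p$I, 4)
    expect_true(all(is.finite(p$se)) && all(p$se >= 0))
  }
})
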