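## Standardized two-stage data-generating model for a two-arm trial with an
## endogenous dose variable, plus the Monte Carlo evaluation harness.
##
## The model, per subject i:
##   Y_i = beta_B B_i + beta_S S_i + eta U_i + eps_i
##   S_i = c B_i + c R_i + c R_i B_i + eta U_i + delta_i
## with B ~ N(0, sigma_B2), U ~ N(0, 1), R ~ Bernoulli(p), all independent,
## and eps, delta independent noise.  The single first-stage coefficient c
## and the error variances are solved so that Var(S) = Var(Y) = 1,
## Cor(S, U) = eta (degree of endogeneity) and Cor(S, W) = kappa with
## W := B + R + RB (instrument strength).

#' Define a simulation scenario
#'
#' @param eta target correlation between the dose \code{S} and the
#'   unobserved confounder \code{U} (degree of endogeneity), in [0, 1).
#' @param kappa target correlation between \code{S} and the combined
#'   instrument score \code{B + R + RB} (instrument strength), in [0, 1).
#' @param n sample size per simulated trial (>= 10).
#' @param beta_S true standardized dose effect (default 1/4).
#' @param beta_B true baseline effect (default 1/4).
#' @param sigma_B2 baseline variance (default 0.3).
#' @param p randomization probability (default 1/2).
#' @return A list of class \code{"scenario"}.
#' @export
scenario <- function(eta, kappa, n, beta_S = 1 / 4, beta_B = 1 / 4,
                     sigma_B2 = 0.3, p = 1 / 2) {
  stopifnot(is.numeric(eta), length(eta) == 1, is.numeric(kappa),
            length(kappa) == 1, is.numeric(n), length(n) == 1)
  if (eta < 0 || eta >= 1 || kappa < 0 || kappa >= 1)
    stop_spslreg("eta and kappa must lie in [0, 1)", "spslreg_contract_error")
  if (n < 10)
    stop_spslreg("n must be at least 10", "spslreg_contract_error")
  if (sigma_B2 <= 0 || p <= 0 || p >= 1)
    stop_spslreg("sigma_B2 must be positive and p in (0, 1)",
                 "spslreg_contract_error")
  structure(list(eta = eta, kappa = kappa, n = as.integer(n),
                 beta_S = beta_S, beta_B = beta_B,
                 sigma_B2 = sigma_B2, p = p),
            class = "scenario")
}

#' The standard 3 x 3 scenario grid
#'
#' Endogeneity \code{eta} in \{0, 0.25, 0.5\} (exogeneity, moderate, high)
#' crossed with instrument strength \code{kappa} in \{0.01, 0.25, 0.5\}
#' (weak, moderately informative, strong).
#'
#' @param n sample size applied to every scenario.
#' @param ... further arguments passed to \code{\link{scenario}}.
#' @return A list of 9 \code{"scenario"} objects, named
#'   \code{"eta<eta>_kappa<kappa>"}.
#' @export
scenario_grid <- function(n, ...) {
  etas <- c(0, 0.25, 0.5)
  kappas <- c(0.01, 0.25, 0.5)
  g <- expand.grid(kappa = kappas, eta = etas)
  out <- lapply(seq_len(nrow(g)),
                function(i) scenario(eta = g$eta[i], kappa = g$kappa[i],
                                     n = n, ...))
  names(out) <- sprintf("eta%s_kappa%s", g$eta, g$kappa)
  out
}

# Closed-form moments of W = B + R + RB under B ~ N(0, sigma_B2) independent
# of R ~ Bernoulli(p):  E[W] = p,  Var(W) = sigma_B2 (1 + 3p) + p(1 - p),
# Cov(B, W) = sigma_B2 (1 + p).  (W = B(1 + R) + R; (1 + R)^2 = 1 + 3R.)
w_moments <- function(sigma_B2, p) {
  list(mean = p,
       var = sigma_B2 * (1 + 3 * p) + p * (1 - p),
       cov_bw = sigma_B2 * (1 + p))
}

#' Solve a scenario's standardization constraints
#'
#' Finds the common first-stage coefficient \code{c} and the error variances
#' so that, under the model's distributional assumptions, the dose and the
#' outcome both have unit marginal variance while \code{Cor(S, U) = eta} and
#' \code{Cor(S, W) = kappa}.  With the three first-stage coefficients set
#' equal, \code{c = kappa / sd(W)}; the remaining moment equations give
#' \deqn{\sigma_\delta^2 = 1 - \eta^2 - \kappa^2,}
#' \deqn{\sigma_\varepsilon^2 = 1 - \beta_B^2\sigma_B^2 - \beta_S^2 - \eta^2
#'   - 2\beta_S\eta^2 - 2\beta_B\beta_S\, c\,\sigma_B^2 (1 + p).}
#' Moments of \code{W} are closed forms from the independence of \code{B}
#' and \code{R}.
#'
#' @param scn a \code{\link{scenario}}.
#' @return The scenario extended with \code{c}, \code{sigma_eps2},
#'   \code{sigma_delta2} and the implied \code{var_W}; class
#'   \code{"solved_scenario"} (inherits \code{"scenario"}).
#' @export
solve_scenario <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  wm <- w_moments(scn$sigma_B2, scn$p)
  cc <- scn$kappa / sqrt(wm$var)
  sigma_delta2 <- 1 - scn$eta^2 - scn$kappa^2
  if (sigma_delta2 <= 0)
    stop_spslreg(sprintf("infeasible scenario: implied Var(delta) = %.4f <= 0 (eta^2 + kappa^2 >= 1)",
                         sigma_delta2),
                 "spslreg_feasibility_error")
  cov_bs <- cc * wm$cov_bw            # Cov(B, S) = c Cov(B, W)
  sigma_eps2 <- 1 - scn$beta_B^2 * scn$sigma_B2 - scn$beta_S^2 - scn$eta^2 -
    2 * scn$beta_S * scn$eta^2 - 2 * scn$beta_B * scn$beta_S * cov_bs
  if (sigma_eps2 <= 0)
    stop_spslreg(sprintf("infeasible scenario: implied Var(eps) = %.4f <= 0",
                         sigma_eps2),
                 "spslreg_feasibility_error")
  out <- c(unclass(scn),
           list(c = cc, sigma_eps2 = sigma_eps2,
                sigma_delta2 = sigma_delta2, var_W = wm$var))
  class(out) <- c("solved_scenario", "scenario")
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario: eta = %g, kappa = %g, n = %d (beta_S = %g, beta_B = %g, sigma_B2 = %g, p = %g)\n",
              x$eta, x$kappa, x$n, x$beta_S, x$beta_B, x$sigma_B2, x$p))
  if (inherits(x, "solved_scenario"))
    cat(sprintf("  solved: c = %.4f, sigma_eps2 = %.4f, sigma_delta2 = %.4f\n",
                x$c, x$sigma_eps2, x$sigma_delta2))
  invisible(x)
}

#' Simulate one trial from a solved scenario
#'
#' Draws \code{n} independent subjects from the standardized two-stage
#' model.  The unobserved confounder \code{U} is returned for
#' oracle/diagnostic use only; the model-fitting view excludes it.
#'
#' @param solved a \code{\link{solve_scenario}} result (a plain
#'   \code{\link{scenario}} is solved on the fly).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A data frame with columns \code{Y, S, B, R, U} and class
#'   \code{"simulated_trial"}; the solved scenario is attached as attribute
#'   \code{"scenario"}.
#' @seealso \code{\link{as_regression_data}} for the estimation view.
#' @export
simulate_trial <- function(solved, seed) {
  if (!inherits(solved, "solved_scenario")) solved <- solve_scenario(solved)
  n <- solved$n
  draws <- with_local_seed(seed, {
    B <- stats::rnorm(n, 0, sqrt(solved$sigma_B2))
    U <- stats::rnorm(n)
    R <- stats::rbinom(n, 1L, solved$p)
    delta <- stats::rnorm(n, 0, sqrt(solved$sigma_delta2))
    eps <- stats::rnorm(n, 0, sqrt(solved$sigma_eps2))
    list(B = B, U = U, R = R, delta = delta, eps = eps)
  })
  S <- solved$c * (draws$B + draws$R + draws$R * draws$B) +
    solved$eta * draws$U + draws$delta
  Y <- solved$beta_B * draws$B + solved$beta_S * S +
    solved$eta * draws$U + draws$eps
  out <- data.frame(Y = Y, S = S, B = draws$B, R = draws$R, U = draws$U)
  attr(out, "scenario") <- solved
  attr(out, "seed") <- seed
  class(out) <- c("simulated_trial", "data.frame")
  out
}

#' Estimation view of a simulated trial
#'
#' Assembles the \code{\link{regression_data}} corresponding to the
#' simulation model: endogenous dose \code{S}, exogenous baseline \code{B},
#' instruments \code{R} and \code{R*B}.  The unobserved confounder is
#' excluded.  The model has no intercept, matching the data-generating
#' equations; set \code{intercept = TRUE} to add one for robustness
#' experiments.
#'
#' @param trial a \code{"simulated_trial"} data frame (or any data frame
#'   with columns \code{Y, S, B, R}).
#' @param intercept add a constant column to the exogenous block?
#' @return A \code{\link{regression_data}} object.
#' @export
as_regression_data <- function(trial, intercept = FALSE) {
  X2 <- if (intercept) cbind(B = trial$B, `(Intercept)` = 1)
        else cbind(B = trial$B)
  regression_data(trial$Y,
                  X1 = cbind(S = trial$S),
                  X2 = X2,
                  Z1 = cbind(R = trial$R, RB = trial$R * trial$B))
}

# Lightweight regression_data constructor for the Monte Carlo inner loop:
# the blocks are trusted (rank failures surface in the fitters and are
# counted as replicate failures).
fast_rd <- function(y, X1, X2, Z1) {
  X <- cbind(X1, X2); Z <- cbind(Z1, X2)
  structure(list(y = y, X1 = X1, X2 = X2, Z1 = Z1, X = X, Z = Z,
                 n = length(y), k1 = ncol(X1), k2 = ncol(X2),
                 k = ncol(X), l1 = ncol(Z1), l = ncol(Z)),
            class = "regression_data")
}

#' Monte Carlo evaluation of the three estimators under one scenario
#'
#' Repeatedly simulates trials from the scenario, fits OLS, TSLS and SPSL on
#' each (no intercept, matching the data-generating model), and summarizes
#' the sampling distributions against the known truth: per-coefficient mean,
#' bias, variance and RMSE, the trace RMSE \code{sqrt(tr MSE)}, the
#' empirical CDF of the dose-effect estimates, and the distribution of the
#' estimated shrinkage weight.
#'
#' Replicate seeds are spawned deterministically from the master seed, so
#' identical \code{(scenario, m, seed)} give identical results.
#'
#' @param scn a \code{\link{scenario}} (solved on the fly).
#' @param m number of Monte Carlo replicates (>= 2).
#' @param seed master seed.
#' @param keep_estimates keep the full m x k estimate matrices?
#' @return An object of class \code{"spsl_mc"}; see Details.
#' @export
run_monte_carlo <- function(scn, m, seed = 1L, keep_estimates = TRUE) {
  if (!is_count(m, min = 2))
    stop_spslreg("m must be an integer >= 2", "spslreg_contract_error")
  solved <- if (inherits(scn, "solved_scenario")) scn else solve_scenario(scn)
  seeds <- spawn_seeds(seed, m)
  k <- 2L
  est <- list(OLS = matrix(NA_real_, m, k), TSLS = matrix(NA_real_, m, k),
              SPSL = matrix(NA_real_, m, k))
  alpha <- rep(NA_real_, m)
  failures <- 0L
  for (t in seq_len(m)) {
    d <- simulate_trial(solved, seeds[t])
    rd <- fast_rd(d$Y, cbind(S = d$S), cbind(B = d$B),
                  cbind(R = d$R, RB = d$R * d$B))
    fit <- tryCatch(fit_spsl(rd), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    est$OLS[t, ] <- coef(fit$diagnostics$ols_fit)
    est$TSLS[t, ] <- coef(fit$diagnostics$tsls_fit)
    est$SPSL[t, ] <- coef(fit)
    alpha[t] <- fit$alpha
  }
  if (failures > 0.01 * m)
    stop_spslreg(sprintf("Monte Carlo harness: %d of %d replicates failed to fit",
                         failures, m),
                 "spslreg_mc_failure_error")
  ok <- stats::complete.cases(est$OLS)
  truth <- c(S = solved$beta_S, B = solved$beta_B)
  summaries <- lapply(est, function(e) mc_summarize(e[ok, , drop = FALSE], truth))
  ecdfs <- lapply(est, function(e) stats::ecdf(e[ok, 1]))
  structure(list(scenario = solved, m = m, seed = seed,
                 truth = truth,
                 summaries = summaries,
                 ecdf_beta_S = ecdfs,
                 alpha_hat = alpha[ok],
                 failures = failures,
                 estimates = if (keep_estimates) lapply(est, function(e)
                   e[ok, , drop = FALSE])),
            class = "spsl_mc")
}

# Per-coefficient Monte Carlo summaries plus trace RMSE with its delta-method
# Monte Carlo standard error.  Variance uses divisor m so that
# RMSE^2 = bias^2 + variance holds exactly.
mc_summarize <- function(e, truth) {
  m <- nrow(e)
  mean_ <- colMeans(e)
  bias <- mean_ - truth
  variance <- colMeans(sweep(e, 2, mean_)^2)
  rmse <- sqrt(bias^2 + variance)
  sq <- sweep(e, 2, truth)^2
  q <- rowSums(sq)                    # per-replicate squared distance
  trace_rmse <- sqrt(mean(q))
  trace_rmse_se <- stats::sd(q) / (2 * sqrt(m) * trace_rmse)
  list(per_coef = data.frame(coef = names(truth), mean = mean_, bias = bias,
                             variance = variance, rmse = rmse,
                             row.names = NULL),
       trace_rmse = trace_rmse,
       trace_rmse_se = trace_rmse_se,
       m = m)
}

#' @export
print.spsl_mc <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo summary: m = %d replicates (%d failures), seed = %d\n",
              x$m, x$failures, x$seed))
  print(x$scenario)
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("%s: trace RMSE = %.*f (MC SE %.*f)\n", nm, digits,
                s$trace_rmse, digits, s$trace_rmse_se))
    print(format(s$per_coef, digits = digits), row.names = FALSE)
  }
  cat(sprintf("alpha_hat: mean = %.4f, sd = %.4f\n",
              mean(x$alpha_hat), stats::sd(x$alpha_hat)))
  invisible(x)
}

#' RMSE comparison plot across estimators
#'
#' @param x an \code{"spsl_mc"} summary.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.spsl_mc <- function(x, ...) {
  r <- vapply(x$summaries, function(s) s$trace_rmse, numeric(1))
  graphics::barplot(r, ylab = "trace RMSE", ...)
  invisible(x)
}
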