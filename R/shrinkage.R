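## The Stein-like combination machinery: cross-squared-error plug-in,
## closed-form shrinkage weight, its empirical counterpart, the SPSL fit and
## pairs-bootstrap standard errors.

#' Plug-in estimate of the cross squared error of OLS and TSLS
#'
#' The cross squared error (CSE) is the expected outer product of the two
#' estimators' deviations from the truth, \code{E[(b_tsls - b)(b_ols - b)']};
#' it is the cross term in the mean squared error of any affine combination
#' of the two.  Under exogenous instruments the analytic covariance of the
#' pair equals \code{sigma2 (X'X)^{-1}} (a consequence of the projection
#' identity \code{X'Xhat = Xhat'Xhat}), so the plug-in estimate is the TSLS
#' residual variance times the OLS bread.
#'
#' @param ols,tsls \code{"estimator_fit"} objects from \code{\link{fit_ols}}
#'   and \code{\link{fit_tsls}} on the same data.
#' @param data the shared \code{\link{regression_data}} (used only for
#'   dimension checks).
#' @return A symmetric positive semi-definite \code{k x k} matrix.
#' @export
estimate_cse <- function(ols, tsls, data = NULL) {
  xtx_inv <- ols$xtx_inv
  if (is.null(xtx_inv))
    stop_spslreg("ols fit does not carry (X'X)^{-1}", "spslreg_contract_error")
  if (length(coef(ols)) != length(coef(tsls)))
    stop_spslreg("fits have different coefficient dimensions",
                 "spslreg_contract_error")
  tsls$sigma2 * xtx_inv
}

#' Risk-optimal shrinkage weight from MSE components
#'
#' The trace mean squared error of the affine combination
#' \code{a * b_tsls + (1 - a) * b_ols} is a quadratic in \code{a}; whenever
#' \code{tr(MSE_tsls - 2 CSE + MSE_ols) > 0} it is strictly convex and its
#' unique minimizer is
#' \deqn{\alpha = \frac{tr(MSE_{ols} - CSE)}{tr(MSE_{tsls} - 2 CSE + MSE_{ols})}.}
#' With the theoretical ingredients (an unbiased TSLS, for which
#' \code{CSE = Cov(b_tsls, b_ols) = Var(b_ols)}), the numerator reduces to
#' the squared OLS bias and the denominator to that bias plus the TSLS
#' variance excess, so the optimal weight lies in [0, 1]; for
#' caller-supplied matrices it need not.
#'
#' @param mse_tsls,mse_ols \code{k x k} mean-squared-error matrices of the
#'   TSLS and OLS estimators.
#' @param cse \code{k x k} cross-squared-error matrix.
#' @param tol degenerate-denominator tolerance.
#' @return The scalar optimal weight on the TSLS estimator.
#' @export
theoretical_alpha <- function(mse_tsls, mse_ols, cse, tol = 1e-12) {
  num <- sum(diag(mse_ols)) - sum(diag(cse))
  den <- sum(diag(mse_tsls)) - 2 * sum(diag(cse)) + sum(diag(mse_ols))
  if (abs(den) < tol)
    stop_spslreg("degenerate shrinkage: the two estimators have equal risk and the MSE is flat in alpha",
                 "spslreg_degenerate_shrinkage_error")
  num / den
}

#' Empirical shrinkage weight and diagnostics
#'
#' Replaces the unknown theoretical quantities in the optimal weight by
#' sample estimates.  The Stein-type shrinkage factor is
#' \code{stein_factor = tau_hat / ||b_ols - b_tsls||^2} with
#' \code{tau_hat = tr(Var(b_tsls) - CSE)} (the estimated variance excess of
#' TSLS over the shared covariance); the denominator is the empirical
#' squared-bias trace of OLS.  The combined estimator shrinks the TSLS fit
#' toward OLS by that fraction of their difference, truncated at OLS (the
#' positive-part rule standard for Stein estimators — without it the weight
#' behaves as \code{1/chi^2} near coincident fits and the combination has
#' unbounded risk).  The resulting TSLS weight is
#' \code{alpha_hat = max(0, 1 - stein_factor)}: strong instruments (small
#' \code{tau_hat}) and a large OLS bias push it toward 1 (TSLS), weak
#' instruments toward 0 (OLS).
#'
#' When the two coefficient vectors coincide (squared distance below
#' \code{tol}) every weight yields the same estimator; \code{alpha_hat} is
#' set to 0 and the \code{degenerate} flag raised.
#'
#' @inheritParams estimate_cse
#' @param cse cross-squared-error matrix, usually from
#'   \code{\link{estimate_cse}}.
#' @param tol squared-distance threshold for the degenerate case.
#' @return An object of class \code{"shrinkage_diagnostics"}: a list with
#'   \code{alpha_hat} (TSLS weight, in [0, 1]), \code{stein_factor}
#'   (unclamped shrinkage fraction), \code{tau_hat}, \code{dist_sq},
#'   \code{cse}, \code{degenerate}, \code{ols_fit}, \code{tsls_fit}.
#' @export
alpha_hat <- function(ols, tsls, cse, tol = 1e-12) {
  if (length(coef(ols)) != length(coef(tsls)))
    stop_spslreg("fits have different coefficient dimensions",
                 "spslreg_contract_error")
  d <- coef(ols) - coef(tsls)
  dist_sq <- sum(d^2)
  tau <- sum(diag(vcov(tsls))) - sum(diag(cse))
  degenerate <- dist_sq < tol
  s <- if (degenerate) Inf else tau / dist_sq
  a <- if (degenerate) 0 else max(0, 1 - s)
  structure(list(alpha_hat = a,
                 stein_factor = s,
                 tau_hat = tau,
                 dist_sq = dist_sq,
                 cse = cse,
                 degenerate = degenerate,
                 ols_fit = ols,
                 tsls_fit = tsls),
            class = "shrinkage_diagnostics")
}

#' @export
print.shrinkage_diagnostics <- function(x, ...) {
  cat(sprintf("Shrinkage diagnostics: alpha_hat = %.4f (TSLS weight), tau_hat = %.4g, ||b_ols - b_tsls||^2 = %.4g%s\n",
              x$alpha_hat, x$tau_hat, x$dist_sq,
              if (x$degenerate) " [degenerate: estimators coincide]" else ""))
  invisible(x)
}

#' Semi-parametric Stein-like (SPSL) combined fit
#'
#' Fits OLS and TSLS, estimates the shrinkage weight, and returns the affine
#' combination \code{b_spsl = alpha_hat * b_tsls + (1 - alpha_hat) * b_ols}.
#' The reported covariance is the plug-in MSE of the combination at the
#' estimated weight,
#' \code{a^2 Var_tsls + 2 a (1 - a) CSE + (1 - a)^2 Var_ols}
#' (it ignores the sampling variability of the weight itself, so the pairs
#' bootstrap of \code{\link{bootstrap_se}} is the recommended standard
#' error).
#'
#' @inheritParams fit_ols
#' @param alpha optional fixed weight overriding the data-driven
#'   \code{alpha_hat} (used mainly for diagnostics and testing).
#' @return An \code{"estimator_fit"} of method \code{"SPSL"} with the
#'   diagnostics attached as \code{$diagnostics}.
#' @export
fit_spsl <- function(data, alpha = NULL) {
  ols <- fit_ols(data)
  tsls <- fit_tsls(data)
  cse <- estimate_cse(ols, tsls, data)
  diag_ <- alpha_hat(ols, tsls, cse)
  a <- if (is.null(alpha)) diag_$alpha_hat else alpha
  beta <- a * coef(tsls) + (1 - a) * coef(ols)
  covariance <- a^2 * vcov(tsls) + 2 * a * (1 - a) * cse +
    (1 - a)^2 * vcov(ols)
  res <- data$y - drop(data$X %*% beta)
  sigma2 <- sum(res^2) / (data$n - data$k)
  fit <- new_estimator_fit("SPSL", beta, covariance, sigma2,
                           data$n - data$k, ols$xtx_inv, tsls$xhx_inv)
  fit$diagnostics <- diag_
  fit$alpha <- a
  fit
}

#' Pairs-bootstrap standard errors for OLS, TSLS or SPSL coefficients
#'
#' Resamples subject rows with replacement, refits the requested estimator on
#' each resample, and returns the elementwise standard deviation of the
#' bootstrap coefficient vectors.  Resamples on which the refit fails (e.g. a
#' rank-deficient resampled design) are discarded and redrawn, up to a total
#' of \code{10 * B} draws.
#'
#' @inheritParams fit_ols
#' @param method one of \code{"OLS"}, \code{"TSLS"}, \code{"SPSL"}.
#' @param B number of bootstrap replications (default 1000).
#' @param seed integer seed governing the resampling.
#' @return A named numeric vector of standard errors with attributes
#'   \code{B}, \code{seed} and \code{failures} (number of discarded
#'   resamples).
#' @export
bootstrap_se <- function(data, method = c("SPSL", "OLS", "TSLS"),
                         B = 1000L, seed = 1L) {
  stopifnot(inherits(data, "regression_data"))
  method <- match.arg(toupper(method[1]), c("SPSL", "OLS", "TSLS"))
  if (!is_count(B, min = 2))
    stop_spslreg("B must be an integer >= 2", "spslreg_contract_error")
  fitter <- switch(method, OLS = fit_ols, TSLS = fit_tsls, SPSL = fit_spsl)
  est <- matrix(NA_real_, B, data$k)
  with_local_seed(seed, {
    got <- 0L; draws <- 0L; failures <- 0L
    while (got < B) {
      if (draws >= 10L * B)
        stop_spslreg(sprintf("bootstrap unstable: %d of %d resamples failed to fit",
                             failures, draws),
                     "spslreg_bootstrap_instability_error",
                     failure_rate = failures / draws)
      idx <- sample.int(data$n, data$n, replace = TRUE)
      draws <- draws + 1L
      fit <- tryCatch(fitter(subset_rows(data, idx)), error = function(e) NULL)
      if (is.null(fit)) { failures <- failures + 1L; next }
      got <- got + 1L
      est[got, ] <- coef(fit)
    }
  })
  se <- apply(est, 2, stats::sd)
  names(se) <- colnames(data$X)
  attr(se, "B") <- B
  attr(se, "seed") <- seed
  attr(se, "failures") <- failures
  se
}
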