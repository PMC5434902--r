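## OLS and TSLS estimation, empirical squared bias, and first-stage
## instrument diagnostics.  Coefficients are always ordered
## [endogenous block; exogenous block], matching X = [X1 X2].

new_estimator_fit <- function(method, coefficients, covariance, sigma2, dof,
                              xtx_inv, xhx_inv = NULL) {
  structure(list(method = method,
                 coefficients = coefficients,
                 covariance = covariance,
                 sigma2 = sigma2,
                 dof = dof,
                 xtx_inv = xtx_inv,
                 xhx_inv = xhx_inv),
            class = "estimator_fit")
}

#' Ordinary least squares fit of the outcome model
#'
#' Solves the normal equations for \code{y = X b + e} with
#' \code{X = [X1 X2]} via a QR decomposition.  The residual variance is
#' \code{sigma2 = RSS / (n - k)} and the coefficient covariance the classical
#' \code{sigma2 (X'X)^{-1}}.  Under endogeneity of \code{X1} this estimator
#' is biased but has the smallest variance of the pair it is later combined
#' with.
#'
#' @param data a \code{\link{regression_data}} object.
#' @return An object of class \code{"estimator_fit"} with elements
#'   \code{method}, \code{coefficients}, \code{covariance}, \code{sigma2}
#'   and \code{dof = n - k}.
#' @seealso \code{\link{fit_tsls}}, \code{\link{fit_spsl}}
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "regression_data"))
  X <- data$X; y <- data$y
  n <- data$n; k <- data$k
  qx <- qr(X)
  if (qx$rank < k)
    stop_spslreg(paste0("X is rank deficient; offending columns: ",
                        paste(dependent_columns(X), collapse = ", ")),
                 "spslreg_identification_error")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - k)
  xtx_inv <- xtx_inverse(qx)
  new_estimator_fit("OLS", beta, sigma2 * xtx_inv, sigma2, n - k, xtx_inv)
}

#' Two-stage least squares fit of the outcome model
#'
#' Projects the full design \code{X = [X1 X2]} onto the column space of the
#' instrument matrix \code{Z = [Z1 X2]} (the projection is applied through a
#' QR decomposition of \code{Z}; the hat matrix is never formed) and
#' regresses the outcome on the projected design \code{Xhat}.  The residual
#' variance uses the residuals of the ORIGINAL design,
#' \code{sigma2 = (y - X bhat)'(y - X bhat) / (n - k)}, and the coefficient
#' covariance is \code{sigma2 (Xhat'Xhat)^{-1}}.
#'
#' @inheritParams fit_ols
#' @return An \code{"estimator_fit"} object (see \code{\link{fit_ols}}).
#' @export
fit_tsls <- function(data) {
  stopifnot(inherits(data, "regression_data"))
  if (data$l1 < data$k1)
    stop_spslreg(sprintf("under-identified: %d instruments for %d endogenous predictors",
                         data$l1, data$k1),
                 "spslreg_identification_error")
  X <- data$X; Z <- data$Z; y <- data$y
  n <- data$n; k <- data$k; l <- data$l
  qz <- qr(Z)
  if (qz$rank < l)
    stop_spslreg(paste0("Z is rank deficient; offending columns: ",
                        paste(dependent_columns(Z), collapse = ", ")),
                 "spslreg_identification_error")
  if (mat_rank(crossprod(Z, X)) < k)
    stop_spslreg("rank(Z'X) < k: instruments do not identify the endogenous block",
                 "spslreg_identification_error")
  Xhat <- qr.fitted(qz, X)
  colnames(Xhat) <- colnames(X)
  qxh <- qr(Xhat)
  beta <- qr.coef(qxh, y)
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - k)
  xhx_inv <- xtx_inverse(qxh)
  # (X'X)^{-1} is retained for the cross-squared-error plug-in.
  xtx_inv <- xtx_inverse(qr(X))
  new_estimator_fit("TSLS", beta, sigma2 * xhx_inv, sigma2, n - k,
                    xtx_inv, xhx_inv)
}

#' Empirical squared bias of a candidate estimator
#'
#' The TSLS estimator is asymptotically unbiased under exogenous instruments,
#' so the deviation of any candidate from it estimates the candidate's bias:
#' the empirical squared-bias matrix is the outer product
#' \code{(b_cand - b_tsls)(b_cand - b_tsls)'}.  Its trace is the squared
#' Euclidean distance between the two coefficient vectors and coincides with
#' the trace of the numerator of the Hausman exogeneity statistic.
#'
#' @param candidate,tsls \code{"estimator_fit"} objects on the same data with
#'   identical coefficient ordering.
#' @return A symmetric positive semi-definite \code{k x k} matrix of rank at
#'   most one.
#' @export
empirical_bias_sq <- function(candidate, tsls) {
  b1 <- coef(candidate); b2 <- coef(tsls)
  if (length(b1) != length(b2))
    stop_spslreg("coefficient vectors have different lengths",
                 "spslreg_contract_error")
  d <- b1 - b2
  tcrossprod(d)
}

#' First-stage partial F statistic for instrument strength
#'
#' Compares the first-stage regression of one endogenous predictor on
#' \code{[Z1 X2]} against the null regression on \code{X2} alone:
#' \code{F = ((RSS0 - RSS1) / l1) / (RSS1 / (n - l))}.  Small values signal
#' weak instruments, which inflate both the variance and the finite-sample
#' bias of TSLS.
#'
#' @inheritParams fit_ols
#' @param endogenous_index which column of \code{X1} the first stage
#'   predicts (default 1).
#' @return A list of class \code{"first_stage_f"} with \code{statistic},
#'   \code{df1 = l1}, \code{df2 = n - l}, \code{endogenous_column} and
#'   \code{p.value}.
#' @export
first_stage_f <- function(data, endogenous_index = 1L) {
  stopifnot(inherits(data, "regression_data"))
  if (data$l1 < 1L)
    stop_spslreg("no instruments supplied", "spslreg_contract_error")
  if (!is_count(endogenous_index) || endogenous_index > data$k1)
    stop_spslreg("endogenous_index out of range", "spslreg_contract_error")
  x <- data$X1[, endogenous_index]
  if (mat_rank(data$Z) < data$l)
    stop_spslreg("instruments are collinear with the exogenous block",
                 "spslreg_identification_error")
  rss1 <- sum(qr.resid(qr(data$Z), x)^2)
  rss0 <- if (data$k2 > 0L) sum(qr.resid(qr(data$X2), x)^2) else sum(x^2)
  df1 <- data$l1
  df2 <- data$n - data$l
  stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  # RSS0 >= RSS1 analytically; clamp tiny negative rounding.
  stat <- max(stat, 0)
  structure(list(statistic = stat, df1 = df1, df2 = df2,
                 endogenous_column = colnames(data$X1)[endogenous_index],
                 p.value = stats::pf(stat, df1, df2, lower.tail = FALSE)),
            class = "first_stage_f")
}

#' @export
print.first_stage_f <- function(x, ...) {
  cat(sprintf("First-stage partial F for %s: F = %.2f, df1 = %d, df2 = %d, p = %.3g\n",
              x$endogenous_column, x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' @export
coef.estimator_fit <- function(object, ...) object$coefficients

#' @export
vcov.estimator_fit <- function(object, ...) object$covariance

#' @export
print.estimator_fit <- function(x, ...) {
  cat(sprintf("%s fit (sigma2 = %.4g, dof = %d)\n", x$method, x$sigma2, x$dof))
  tab <- cbind(Estimate = x$coefficients,
               `Std. Error` = sqrt(pmax(diag(x$covariance), 0)))
  print(tab, ...)
  invisible(x)
}
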