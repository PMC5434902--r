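## Chained-equations multiple imputation with Bayesian normal-linear
## conditional models, MAR amputation for testing, and Rubin's-rules pooling.

#' Impose missing-at-random missingness on a complete table
#'
#' Test fixture generator: deletes values according to a logistic
#' missingness model driven only by fully observed columns, so the
#' missing-at-random (MAR) assumption holds by construction.
#'
#' @param table a complete data frame.
#' @param mspec a list of missingness rules; each rule is a list with
#'   \code{target} (column to receive missing values), \code{intercept}
#'   (logit-scale), and \code{slopes} (named numeric vector over predictor
#'   columns).  Predictor columns must not themselves be targets.
#' @param seed integer seed.
#' @return The table with \code{NA}s inserted, class
#'   \code{"incomplete_table"}, with attributes \code{mask} (logical matrix,
#'   TRUE = missing) and \code{missing_rate} (named realized fractions).
#' @examples
#' d <- simulate_trial(scenario(eta = 0, kappa = 0.5, n = 200), seed = 1)
#' inc <- ampute_mar(d, list(list(target = "Y", intercept = -1,
#'                                slopes = c(B = 1))), seed = 2)
#' attr(inc, "missing_rate")
#' @export
ampute_mar <- function(table, mspec, seed) {
  stopifnot(is.data.frame(table))
  targets <- vapply(mspec, `[[`, character(1), "target")
  if (anyDuplicated(targets))
    stop_spslreg("duplicate amputation targets", "spslreg_contract_error")
  out <- as.data.frame(table)
  mask <- matrix(FALSE, nrow(out), ncol(out),
                 dimnames = list(NULL, names(out)))
  ks <- spawn_seeds(seed, length(mspec))
  for (i in seq_along(mspec)) {
    rule <- mspec[[i]]
    if (!rule$target %in% names(out))
      stop_spslreg(paste0("unknown amputation target: ", rule$target),
                   "spslreg_contract_error")
    preds <- names(rule$slopes)
    if (length(preds)) {
      if (!all(preds %in% names(out)))
        stop_spslreg("missingness predictors absent from the table",
                     "spslreg_contract_error")
      if (any(preds %in% targets))
        stop_spslreg(paste0("missingness may only depend on fully observed columns; offending predictors: ",
                            paste(intersect(preds, targets), collapse = ", ")),
                     "spslreg_contract_error")
      lp <- rule$intercept +
        as.matrix(out[preds]) %*% rule$slopes
    } else lp <- rep(rule$intercept, nrow(out))
    pmiss <- stats::plogis(drop(lp))
    drop_i <- with_local_seed(ks[i], stats::runif(nrow(out)) < pmiss)
    mask[drop_i, rule$target] <- TRUE
    out[drop_i, rule$target] <- NA_real_
  }
  if (!any(colSums(mask) == 0L))
    stop_spslreg("at least one column must remain fully observed",
                 "spslreg_contract_error")
  if (any(colSums(mask) == nrow(out)))
    stop_spslreg(paste0("column(s) entirely missing after amputation: ",
                        paste(names(out)[colSums(mask) == nrow(out)],
                              collapse = ", ")),
                 "spslreg_contract_error")
  if (any(rowSums(mask) == ncol(out)))
    stop_spslreg("some rows would be entirely missing", "spslreg_contract_error")
  structure(out, mask = mask,
            missing_rate = colMeans(mask),
            class = c("incomplete_table", "data.frame"))
}

#' Multiple imputation by chained equations
#'
#' Fills in missing values by cycling univariate Bayesian normal-linear
#' regressions: each incomplete column is regressed on all other columns
#' (current completed values, plus an intercept); the residual variance and
#' coefficients are drawn from their posterior under the standard
#' noninformative prior, and the missing entries are drawn from the
#' resulting predictive distribution.  The Bayesian draws make the \code{I}
#' completed copies differ, as proper multiple imputation requires.
#' Columns whose observed values are all 0/1 are imputed on the linear
#' predictor and thresholded at 1/2 (reported via a message).
#'
#' @param table a data frame with \code{NA}s (e.g. from
#'   \code{\link{ampute_mar}}), or a complete one (returned unchanged
#'   \code{I} times).
#' @param I number of imputed copies (>= 2).
#' @param sweeps full cycles over the incomplete columns per copy
#'   (default 10).
#' @param seed integer seed.
#' @return A list of \code{I} completed data frames, with attribute
#'   \code{"seed"}.
#' @export
impute_chained <- function(table, I = 100L, sweeps = 10L, seed = 1L) {
  stopifnot(is.data.frame(table))
  if (!is_count(I, 2) || !is_count(sweeps, 1))
    stop_spslreg("I must be >= 2 and sweeps >= 1", "spslreg_contract_error")
  dat <- as.data.frame(table)[]
  num <- vapply(dat, is.numeric, logical(1))
  if (!all(num))
    stop_spslreg("all columns must be numeric for normal-linear imputation",
                 "spslreg_contract_error")
  miss_cols <- names(dat)[colSums(is.na(dat)) > 0L]
  if (length(miss_cols) == 0L)
    return(structure(replicate(I, dat, simplify = FALSE), seed = seed))
  if (any(rowSums(is.na(dat)) == ncol(dat)))
    stop_spslreg("rows entirely missing cannot be imputed",
                 "spslreg_contract_error")
  binary <- vapply(dat, function(x) all(stats::na.omit(x) %in% c(0, 1)),
                   logical(1))
  if (any(binary[miss_cols]))
    message("binary column(s) imputed via thresholded normal draw: ",
            paste(miss_cols[binary[miss_cols]], collapse = ", "))
  seeds <- spawn_seeds(seed, I)
  copies <- lapply(seq_len(I), function(i)
    with_local_seed(seeds[i],
                    impute_once(dat, miss_cols, sweeps, binary)))
  structure(copies, seed = seed)
}

# One completed copy: initialize by resampling observed values, then cycle
# Bayesian normal-linear draws.
impute_once <- function(dat, miss_cols, sweeps, binary) {
  cur <- dat
  for (j in miss_cols) {
    mis <- is.na(cur[[j]])
    obs_vals <- cur[[j]][!mis]
    cur[[j]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
  }
  for (s in seq_len(sweeps)) {
    for (j in miss_cols) {
      mis <- is.na(dat[[j]])
      others <- setdiff(names(dat), j)
      X <- cbind(1, as.matrix(cur[others]))
      xo <- X[!mis, , drop = FALSE]
      yo <- dat[[j]][!mis]
      qx <- qr(xo)
      if (qx$rank < ncol(xo))
        stop_spslreg(paste0("conditional imputation model for column '", j,
                            "' is rank deficient"),
                     "spslreg_identification_error")
      bhat <- qr.coef(qx, yo)
      res <- yo - drop(xo %*% bhat)
      df <- length(yo) - ncol(xo)
      if (df < 1L)
        stop_spslreg(paste0("too few observed rows to impute column '", j, "'"),
                     "spslreg_insufficient_data_error")
      sigma2_star <- sum(res^2) / stats::rchisq(1, df)
      r_inv <- xtx_inverse(qx)
      bstar <- bhat + drop(chol_psd(sigma2_star * r_inv) %*%
                             stats::rnorm(length(bhat)))
      xm <- X[mis, , drop = FALSE]
      draw <- drop(xm %*% bstar) +
        stats::rnorm(sum(mis), 0, sqrt(sigma2_star))
      if (binary[[j]]) draw <- as.numeric(draw >= 0.5)
      cur[[j]][mis] <- draw
    }
  }
  cur
}

# Cholesky-like factor of a symmetric PSD matrix, tolerant of zero/tiny
# eigenvalues (e.g. zero residual variance).
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Pool per-imputation fits by Rubin's rules
#'
#' Combines \code{I} estimates of the same coefficient vector: the pooled
#' estimate is the arithmetic mean, and the pooled squared standard error is
#' the mean within-imputation variance plus \code{(I + 1) / I} times the
#' between-imputation variance
#' \code{B_j = sum_i (b_ji - mean_j)^2 / (I - 1)} (equivalently the
#' \code{(I + 1) / (I (I - 1))} factor on the sum of squared deviations).
#'
#' @param fits a list of \code{I >= 2} per-imputation results, each either an
#'   \code{"estimator_fit"} or a list with \code{coefficients} and
#'   \code{variance} (per-coefficient within-imputation variances, or a
#'   covariance matrix whose diagonal is used).
#' @return An object of class \code{"pooled_fit"}: list with \code{I},
#'   \code{coefficients}, \code{se}, \code{within}, \code{between},
#'   \code{estimates} (I x k matrix).
#' @export
pool_rubin <- function(fits) {
  I <- length(fits)
  if (I < 2L)
    stop_spslreg("need at least 2 imputations to pool", "spslreg_contract_error")
  get_coef <- function(f) if (inherits(f, "estimator_fit")) coef(f) else f$coefficients
  get_var <- function(f) {
    v <- if (inherits(f, "estimator_fit")) vcov(f) else f$variance
    if (is.matrix(v)) diag(v) else v
  }
  cf <- lapply(fits, get_coef)
  nms <- names(cf[[1]])
  kk <- length(cf[[1]])
  if (!all(vapply(cf, length, integer(1)) == kk) ||
      (!is.null(nms) && !all(vapply(cf, function(b)
        identical(names(b), nms), logical(1)))))
    stop_spslreg("per-imputation fits have inconsistent coefficient sets",
                 "spslreg_contract_error")
  est <- do.call(rbind, cf)
  wv <- do.call(rbind, lapply(fits, get_var))
  pooled <- colMeans(est)
  within <- colMeans(wv)
  between <- apply(est, 2, stats::var)        # divisor I - 1
  se <- sqrt(within + (I + 1) / I * between)
  structure(list(I = I, coefficients = pooled, se = se,
                 within = within, between = between, estimates = est),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Rubin's-rules pooled fit over I = %d imputations\n", x$I))
  print(round(cbind(Estimate = x$coefficients, `Pooled SE` = x$se), digits))
  invisible(x)
}

#' @export
coef.pooled_fit <- function(object, ...) object$coefficients

#' Impute an incomplete trial and pool OLS/TSLS/SPSL fits
#'
#' Convenience workflow: chained-equations imputation of an incomplete
#' table, estimator fits on every completed copy using the given variable
#' roles, and Rubin's-rules pooling per estimator.  Within-imputation
#' variances are the analytic ones for OLS and TSLS; for SPSL they are pairs
#' bootstrap variances within each imputed dataset (\code{B} resamples), the
#' construction matching how combined-estimator uncertainty is usually
#' reported.
#'
#' @param table an incomplete data frame (missing = \code{NA}).
#' @param roles a list with character fields \code{outcome},
#'   \code{endogenous}, \code{exogenous} (may be empty), \code{instruments}.
#' @param estimators subset of \code{c("OLS", "TSLS", "SPSL")}.
#' @param I,sweeps,seed imputation settings (see
#'   \code{\link{impute_chained}}).
#' @param B bootstrap replications for the SPSL within-imputation variance.
#' @return A named list of \code{"pooled_fit"} objects, one per estimator,
#'   with the completed copies attached as attribute \code{"imputations"}.
#' @export
impute_fit <- function(table, roles, estimators = c("OLS", "TSLS", "SPSL"),
                       I = 100L, sweeps = 10L, seed = 1L, B = 1000L) {
  estimators <- match.arg(toupper(estimators), c("OLS", "TSLS", "SPSL"),
                          several.ok = TRUE)
  roles <- validate_roles(roles, names(table))
  copies <- impute_chained(table, I = I, sweeps = sweeps, seed = seed)
  boot_seeds <- spawn_seeds(seed + 1L, length(copies))
  per_est <- lapply(estimators, function(meth) {
    fits <- lapply(seq_along(copies), function(i) {
      rd <- roles_to_data(copies[[i]], roles)
      fit <- switch(meth, OLS = fit_ols(rd), TSLS = fit_tsls(rd),
                    SPSL = fit_spsl(rd))
      if (meth == "SPSL") {
        se <- bootstrap_se(rd, "SPSL", B = B, seed = boot_seeds[i])
        list(coefficients = coef(fit), variance = as.numeric(se)^2)
      } else fit
    })
    pool_rubin(fits)
  })
  names(per_est) <- estimators
  attr(per_est, "imputations") <- copies
  per_est
}

validate_roles <- function(roles, cols) {
  need <- c("outcome", "endogenous", "instruments")
  if (!all(need %in% names(roles)))
    stop_spslreg(paste0("roles must name: ", paste(need, collapse = ", ")),
                 "spslreg_role_error")
  if (is.null(roles$exogenous)) roles$exogenous <- character(0)
  all_roles <- c(roles$outcome, roles$endogenous, roles$exogenous,
                 roles$instruments)
  if (anyDuplicated(all_roles))
    stop_spslreg("role lists must be disjoint", "spslreg_role_error")
  missing_cols <- setdiff(all_roles, cols)
  if (length(missing_cols))
    stop_spslreg(paste0("role columns absent from data: ",
                        paste(missing_cols, collapse = ", ")),
                 "spslreg_role_error")
  if (length(roles$outcome) != 1L)
    stop_spslreg("exactly one outcome column required", "spslreg_role_error")
  roles
}

roles_to_data <- function(df, roles, intercept = FALSE) {
  X2 <- if (length(roles$exogenous))
    as.matrix(df[roles$exogenous]) else NULL
  if (intercept) {
    X2 <- cbind(X2, `(Intercept)` = rep(1, nrow(df)))
  }
  regression_data(df[[roles$outcome]],
                  X1 = as.matrix(df[roles$endogenous]),
                  X2 = X2,
                  Z1 = if (length(roles$instruments))
                    as.matrix(df[roles$instruments]) else NULL)
}
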