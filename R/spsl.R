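#' Fit a dose-response instrumental-variable model by OLS, TSLS and SPSL
#'
#' The main model-fitting interface.  The model is specified by a two-part
#' formula \code{y ~ predictors | instruments}: the right-hand parts are
#' expanded separately, terms appearing in both parts form the exogenous
#' block \code{X2}, terms only in the first part are the endogenous block
#' \code{X1}, and terms only in the second part are the instruments
#' \code{Z1}.  This is the usual instrumental-variable formula convention;
#' e.g. for a two-arm psychotherapy trial with outcome score \code{panss},
#' attended sessions \code{sessions} (endogenous), baseline score
#' \code{base} and randomization arm \code{arm}:
#'
#' \preformatted{spsl(panss ~ sessions + base | arm + arm:base + base, data)}
#'
#' All three estimators are computed: ordinary least squares (efficient but
#' biased when the dose is confounded), two-stage least squares
#' (asymptotically unbiased, but noisier, the more so the weaker the
#' instruments), and the semi-parametric Stein-like combination, an affine
#' mix of the two whose weight minimizes the estimated trace mean squared
#' error.
#'
#' @param formula a two-part formula \code{y ~ x1 + x2 | z1 + x2}.  An
#'   intercept is included unless removed with \code{- 1} (remove it in both
#'   parts for a no-intercept model).
#' @param data a data frame containing the variables.
#' @param subset,na.action as in \code{\link[stats]{lm}}; the default
#'   \code{na.action} fails on missing values — use the imputation workflow
#'   (\code{\link{impute_fit}}) for incomplete data.
#' @param bootstrap number of pairs-bootstrap replications for the SPSL
#'   standard errors; 0 skips the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @return An object of class \code{"spsl"}: a list with the three
#'   \code{"estimator_fit"}s (\code{ols}, \code{tsls}, \code{spsl}), the
#'   shrinkage \code{diagnostics}, per-endogenous-column
#'   \code{first_stage} partial-F results, the \code{\link{regression_data}}
#'   used, and optionally \code{bootstrap} standard errors.
#' @examples
#' d <- simulate_trial(solve_scenario(scenario(eta = 0.25, kappa = 0.5,
#'                                             n = 300)), seed = 7)
#' fit <- spsl(Y ~ S + B - 1 | R + R:B + B - 1, data = d)
#' fit
#' coef(fit)                 # SPSL coefficients
#' coef(fit, which = "tsls")
#' @export
spsl <- function(formula, data, subset = NULL, na.action = stats::na.fail,
                 bootstrap = 0L, seed = 1L) {
  cl <- match.call()
  f <- Formula::as.Formula(formula)
  if (length(f)[2] != 2L)
    stop_spslreg("formula must have two right-hand parts: y ~ predictors | instruments",
                 "spslreg_contract_error")
  mf <- match.call(expand.dots = FALSE)
  m <- match(c("formula", "data", "subset", "na.action"), names(mf), 0L)
  mf <- mf[c(1L, m)]
  mf$formula <- f
  mf$drop.unused.levels <- TRUE
  mf[[1L]] <- quote(stats::model.frame)
  mf <- eval(mf, parent.frame())

  y <- stats::model.response(mf)
  Xall <- stats::model.matrix(f, mf, rhs = 1)
  Zall <- stats::model.matrix(f, mf, rhs = 2)
  exo <- intersect(colnames(Xall), colnames(Zall))
  endo <- setdiff(colnames(Xall), exo)
  inst <- setdiff(colnames(Zall), exo)
  if (length(endo) == 0L)
    stop_spslreg("no endogenous predictors: every first-part term also appears among the instruments",
                 "spslreg_contract_error")
  rd <- regression_data(y,
                        X1 = Xall[, endo, drop = FALSE],
                        X2 = Xall[, exo, drop = FALSE],
                        Z1 = Zall[, inst, drop = FALSE])
  out <- spsl_fit_all(rd, bootstrap = bootstrap, seed = seed)
  out$call <- cl
  out$formula <- f
  out
}

# Fit OLS + TSLS + SPSL and diagnostics on assembled regression data.
spsl_fit_all <- function(rd, bootstrap = 0L, seed = 1L) {
  sp <- fit_spsl(rd)
  fs <- lapply(seq_len(rd$k1), function(j) first_stage_f(rd, j))
  names(fs) <- colnames(rd$X1)
  boot <- NULL
  if (bootstrap > 0L)
    boot <- bootstrap_se(rd, "SPSL", B = bootstrap, seed = seed)
  structure(list(ols = sp$diagnostics$ols_fit,
                 tsls = sp$diagnostics$tsls_fit,
                 spsl = sp,
                 diagnostics = sp$diagnostics,
                 first_stage = fs,
                 bootstrap = boot,
                 data = rd),
            class = "spsl")
}

#' @export
print.spsl <- function(x, digits = 4, ...) {
  cat("Stein-like combined instrumental-variable fit\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("n = %d, endogenous: %s\n", x$data$n,
              paste(colnames(x$data$X1), collapse = ", ")))
  tab <- cbind(OLS = coef(x$ols), TSLS = coef(x$tsls), SPSL = coef(x$spsl))
  print(round(tab, digits))
  d <- x$diagnostics
  cat(sprintf("alpha_hat = %.*f%s\n", digits, d$alpha_hat,
              if (d$degenerate) " [degenerate: OLS = TSLS]" else ""))
  invisible(x)
}

#' @export
coef.spsl <- function(object, which = c("spsl", "ols", "tsls"), ...) {
  coef(object[[match.arg(which)]])
}

#' @export
vcov.spsl <- function(object, which = c("spsl", "ols", "tsls"), ...) {
  vcov(object[[match.arg(which)]])
}

#' @export
fitted.spsl <- function(object, which = c("spsl", "ols", "tsls"), ...) {
  drop(object$data$X %*% coef(object, which))
}

#' @export
residuals.spsl <- function(object, which = c("spsl", "ols", "tsls"), ...) {
  object$data$y - fitted(object, which)
}

#' @export
nobs.spsl <- function(object, ...) object$data$n

#' Predictions from a Stein-like combined fit
#'
#' @param object an \code{"spsl"} fit.
#' @param newdata optional data frame; when omitted, fitted values are
#'   returned.  Prediction uses the second-stage linear predictor with the
#'   selected estimator's coefficients.
#' @param which estimator whose coefficients to use.
#' @param ... unused.
#' @export
predict.spsl <- function(object, newdata = NULL,
                         which = c("spsl", "ols", "tsls"), ...) {
  which <- match.arg(which)
  if (is.null(newdata)) return(fitted(object, which))
  if (is.null(object$formula))
    stop_spslreg("fit was not created through the formula interface; no terms to evaluate",
                 "spslreg_contract_error")
  f <- object$formula
  mf <- stats::model.frame(stats::delete.response(stats::terms(f, rhs = 1)),
                           newdata)
  Xall <- stats::model.matrix(stats::delete.response(stats::terms(f, rhs = 1)),
                              mf)
  cols <- c(colnames(object$data$X1), colnames(object$data$X2))
  missing_cols <- setdiff(cols, colnames(Xall))
  if (length(missing_cols))
    stop_spslreg(paste0("newdata lacks model columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "spslreg_contract_error")
  drop(Xall[, cols, drop = FALSE] %*% coef(object, which))
}

#' @export
summary.spsl <- function(object, ...) {
  mk <- function(fit, se = sqrt(pmax(diag(vcov(fit)), 0))) {
    cbind(Estimate = coef(fit), `Std. Error` = se)
  }
  out <- list(ols = mk(object$ols), tsls = mk(object$tsls),
              spsl = mk(object$spsl),
              spsl_se_type = "plug-in")
  if (!is.null(object$bootstrap)) {
    out$spsl[, "Std. Error"] <- as.numeric(object$bootstrap)
    out$spsl_se_type <- sprintf("pairs bootstrap (B = %d)",
                                attr(object$bootstrap, "B"))
  }
  out$diagnostics <- object$diagnostics
  out$first_stage <- object$first_stage
  out$n <- object$data$n
  class(out) <- "summary.spsl"
  out
}

#' @export
print.summary.spsl <- function(x, digits = 4, ...) {
  for (w in c("ols", "tsls", "spsl")) {
    cat(toupper(w), if (w == "spsl") sprintf("(SE: %s)", x$spsl_se_type), "\n")
    print(round(x[[w]], digits))
    cat("\n")
  }
  print(x$diagnostics)
  for (fs in x$first_stage) print(fs)
  invisible(x)
}

#' Coefficient comparison plot for a Stein-like combined fit
#'
#' Plots the OLS, TSLS and SPSL estimates for each coefficient with +/- 2 SE
#' bars, showing how the combined estimator interpolates its components.
#'
#' @param x an \code{"spsl"} fit.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.spsl <- function(x, ...) {
  s <- summary(x)
  k <- nrow(s$ols)
  est <- rbind(s$ols[, 1], s$tsls[, 1], s$spsl[, 1])
  se <- rbind(s$ols[, 2], s$tsls[, 2], s$spsl[, 2])
  xpos <- rep(seq_len(k), each = 3) + c(-0.15, 0, 0.15)
  est_v <- as.vector(est); se_v <- as.vector(se)
  graphics::plot(xpos, est_v, pch = rep(c(1, 2, 19), k),
                 xaxt = "n", xlab = "", ylab = "estimate",
                 ylim = range(est_v - 2 * se_v, est_v + 2 * se_v), ...)
  graphics::segments(xpos, est_v - 2 * se_v, xpos, est_v + 2 * se_v)
  graphics::axis(1, at = seq_len(k), labels = rownames(s$ols), las = 2)
  graphics::legend("topright", legend = c("OLS", "TSLS", "SPSL"),
                   pch = c(1, 2, 19), bty = "n")
  invisible(x)
}
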