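#' Assemble the blocks of a two-stage regression model
#'
#' Collects the outcome and the partitioned design of an instrumental-variable
#' regression: the outcome is modelled as \code{y = X1 b1 + X2 b2 + e}, where
#' the \code{X1} block contains predictors suspected of correlation with the
#' error (endogenous, e.g. the number of therapy sessions received) and
#' \code{X2} contains exogenous covariates.  The first stage regresses
#' \code{X1} on the instruments \code{Z1} together with \code{X2}; the full
#' instrument matrix is \code{Z = [Z1 X2]}.
#'
#' No intercept is added implicitly: include a constant column in \code{X2}
#' if the model should have one.
#'
#' @param y numeric outcome vector of length \code{n}.
#' @param X1 endogenous predictor block, \code{n x k1} matrix (or vector).
#' @param X2 exogenous predictor block, \code{n x k2} matrix; may have zero
#'   columns.
#' @param Z1 instrument block, \code{n x l1} matrix; may have zero columns
#'   when only ordinary least squares is intended.
#' @return An object of class \code{"regression_data"}: a list with the
#'   validated blocks plus the assembled \code{X = [X1 X2]},
#'   \code{Z = [Z1 X2]} and the dimensions \code{n, k1, k2, k, l1, l}.
#' @examples
#' set.seed(1)
#' n <- 50
#' z <- rnorm(n); u <- rnorm(n)
#' x <- z + u + rnorm(n)
#' y <- 0.5 * x + u + rnorm(n)
#' d <- regression_data(y, X1 = cbind(x = x),
#'                      X2 = cbind(intercept = 1),
#'                      Z1 = cbind(z = z))
#' d$n; d$k; d$l
#' @export
regression_data <- function(y, X1, X2 = NULL, Z1 = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X1 <- as_block(X1, n, "X1")
  X2 <- as_block(X2, n, "X2")
  Z1 <- as_block(Z1, n, "Z1")
  if (anyNA(y) || anyNA(X1) || anyNA(X2) || anyNA(Z1))
    stop_spslreg("missing values are not allowed in regression data; impute first",
                 "spslreg_missing_values_error")

  k1 <- ncol(X1); k2 <- ncol(X2); l1 <- ncol(Z1)
  k <- k1 + k2; l <- l1 + k2
  if (k1 < 1L)
    stop_spslreg("X1 must contain at least one predictor column",
                 "spslreg_contract_error")
  nms <- c(colnames(X1), colnames(X2), colnames(Z1))
  if (anyDuplicated(nms))
    stop_spslreg(paste0("column names must be unique across blocks; duplicated: ",
                        paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                 "spslreg_contract_error")

  X <- cbind(X1, X2)
  Z <- cbind(Z1, X2)
  if (n <= max(k, l))
    stop_spslreg(sprintf("insufficient data: n = %d rows but the model needs more than max(k = %d, l = %d)",
                         n, k, l),
                 "spslreg_insufficient_data_error")
  if (mat_rank(X) < k)
    stop_spslreg(paste0("design matrix X is rank deficient; offending columns: ",
                        paste(dependent_columns(X), collapse = ", ")),
                 "spslreg_identification_error")
  if (l1 > 0L && mat_rank(Z) < l)
    stop_spslreg(paste0("instrument matrix Z is rank deficient; offending columns: ",
                        paste(dependent_columns(Z), collapse = ", ")),
                 "spslreg_identification_error")

  structure(list(y = y, X1 = X1, X2 = X2, Z1 = Z1, X = X, Z = Z,
                 n = n, k1 = k1, k2 = k2, k = k, l1 = l1, l = l),
            class = "regression_data")
}

as_block <- function(m, n, what) {
  if (is.null(m)) {
    m <- matrix(numeric(0), nrow = n, ncol = 0)
  } else if (is.null(dim(m))) {
    m <- matrix(as.numeric(m), ncol = 1)
    colnames(m) <- what
  } else {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
  }
  if (nrow(m) != n)
    stop_spslreg(sprintf("%s has %d rows but y has length %d", what, nrow(m), n),
                 "spslreg_contract_error")
  if (ncol(m) > 0L && is.null(colnames(m)))
    colnames(m) <- paste0(what, ".", seq_len(ncol(m)))
  m
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("Two-stage regression data: n = %d\n", x$n))
  cat(sprintf("  endogenous (k1 = %d): %s\n", x$k1,
              paste(colnames(x$X1), collapse = ", ")))
  cat(sprintf("  exogenous  (k2 = %d): %s\n", x$k2,
              if (x$k2) paste(colnames(x$X2), collapse = ", ") else "<none>"))
  cat(sprintf("  instruments (l1 = %d): %s\n", x$l1,
              if (x$l1) paste(colnames(x$Z1), collapse = ", ") else "<none>"))
  invisible(x)
}

# Subset rows (used by the pairs bootstrap); revalidation is deferred to the
# fitting routines, which check rank on the resampled design.
subset_rows <- function(data, idx) {
  structure(list(y = data$y[idx],
                 X1 = data$X1[idx, , drop = FALSE],
                 X2 = data$X2[idx, , drop = FALSE],
                 Z1 = data$Z1[idx, , drop = FALSE],
                 X = data$X[idx, , drop = FALSE],
                 Z = data$Z[idx, , drop = FALSE],
                 n = length(idx), k1 = data$k1, k2 = data$k2, k = data$k,
                 l1 = data$l1, l = data$l),
            class = "regression_data")
}
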