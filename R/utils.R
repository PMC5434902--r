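## Internal helpers shared across the package.

# Raise a classed condition so callers (and the CLI) can map errors to codes.
stop_spslreg <- function(message, class, ...) {
  stop(errorCondition(message,
                      class = c(class, "spslreg_error", "error"),
                      ...))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All randomness in the package flows
# through this helper so no global RNG state leaks.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Numerical rank via singular values, relative tolerance 1e-10 * sigma_max.
mat_rank <- function(m, tol = 1e-10) {
  if (is.null(dim(m))) m <- as.matrix(m)
  if (ncol(m) == 0L) return(0L)
  d <- svd(m, nu = 0, nv = 0)$d
  sum(d > tol * d[1])
}

# Columns of `m` that are linearly dependent on the preceding ones, by QR
# pivoting; used to name offenders in identification errors.
dependent_columns <- function(m) {
  qx <- qr(m)
  if (qx$rank == ncol(m)) return(character(0))
  bad <- qx$pivot[seq.int(qx$rank + 1L, ncol(m))]
  nm <- colnames(m)
  if (is.null(nm)) paste0("column ", bad) else nm[bad]
}

# (M'M)^{-1} from a QR decomposition, honouring column pivoting.
xtx_inverse <- function(qx) {
  p <- ncol(qx$qr)
  r <- qr.R(qx)[seq_len(p), , drop = FALSE]
  inv <- chol2inv(r)
  piv <- qx$pivot
  out <- matrix(0, p, p)
  out[piv, piv] <- inv
  dimnames(out) <- list(colnames(qx$qr), colnames(qx$qr))
  out
}

# Derive a vector of independent 31-bit replicate seeds from a master seed.
spawn_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max, n))
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}
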