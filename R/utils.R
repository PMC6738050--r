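# Internal numerical helpers shared across modules.

# Truncated-normal draws via inverse-CDF; sd = 0 degenerates to the mean.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) by Golub-Welsch:
# eigen-decomposition of the symmetric Jacobi matrix. Exact for polynomials
# of degree 2n-1; used to marginalise survival over a Gaussian linear
# predictor without Monte Carlo.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E_X[f(X)] for X ~ N(0, var), f vectorised.
gh_expect <- function(f, var, n_nodes = 40) {
  gh <- gauss_hermite(n_nodes)
  x <- sqrt(2 * var) * gh$nodes
  drop(crossprod(gh$weights / sqrt(pi), f(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kinmr <- function(...) stop(sprintf(...), call. = FALSE)

# Column presence check for file readers; names the missing column.
require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_kinmr("%s is missing required column(s): %s", what,
               paste(miss, collapse = ", "))
  invisible(df)
}
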