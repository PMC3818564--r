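# Generalized least squares core shared by the lambda signal estimator and
# the PGLS regression: profile log-likelihood with beta and sigma2 profiled
# out, and the deterministic lambda search (grid pre-scan + Brent).

#' Profile log-likelihood of a GLS model
#'
#' Computes the maximum-likelihood estimates of the coefficients and the
#' scale, and the profiled multivariate-normal log-likelihood, for the model
#' `y ~ N(X beta, sigma2 * V)`:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, `sigma2 = e' V^-1 e / n`, and
#' `lnL = -0.5 * (n log(2 pi sigma2) + log|V| + n)`.
#'
#' A numerically perfect fit (`sigma2` indistinguishable from zero) has an
#' unbounded likelihood and raises an error rather than returning `Inf`.
#'
#' @param y Response vector, ordered as the rows of `V`.
#' @param X Design matrix (full column rank), same row order.
#' @param V Positive-definite covariance structure (e.g. from [phylo_vcv()],
#'   possibly transformed by [lambda_vcv()]).
#' @return List with `lnL`, `beta` (named), and `sigma2`.
#' @export
gls_profile_loglik <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  R <- tryCatch(chol(V), error = function(e) {
    stop("`V` is not positive definite", call. = FALSE)
  })
  # whiten: V = R'R, so backsolve with R' maps to iid errors
  wy <- backsolve(R, y, transpose = TRUE)
  wX <- backsolve(R, X, transpose = TRUE)
  qx <- qr(wX)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient",
                              call. = FALSE)
  beta <- qr.coef(qx, wy)
  quad <- sum(qr.resid(qx, wy)^2) # e' V^-1 e
  sigma2 <- quad / n
  if (sigma2 <= 1e-12 * (mean(y^2) + 1e-12)) {
    stop("residual variance is numerically zero (perfect fit); ",
         "the profile likelihood is unbounded", call. = FALSE)
  }
  logdetV <- 2 * sum(log(diag(R)))
  lnL <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  list(lnL = lnL, beta = setNames(as.numeric(beta), colnames(X)),
       sigma2 = sigma2)
}

# Deterministic maximization of the profile likelihood over lambda in [0, 1]:
# a 101-point grid pre-scan guards against local optima, then Brent refines
# within the bracketing interval. Ties (flat likelihoods, e.g. star trees)
# break toward lambda = 0.
.lambda_profile <- function(y, X, V, ngrid = 101L) {
  f <- function(lam) gls_profile_loglik(y, X, lambda_vcv(V, lam))$lnL
  grid <- seq(0, 1, length.out = ngrid)
  ll <- vapply(grid, f, numeric(1))
  i <- which(ll >= max(ll) - 1e-10)[1L]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(ngrid, i + 1L)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective > ll[i] + 1e-10) {
    list(lambda = opt$maximum, lnL = opt$objective)
  } else {
    list(lambda = grid[i], lnL = ll[i])
  }
}
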