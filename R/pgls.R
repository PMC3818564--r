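#' Phylogenetic generalized least squares regression
#'
#' Fits `formula` by GLS with error covariance `sigma2 * V(lambda)`, where
#' `V` is the phylogenetic covariance of `tree` and `lambda` multiplies its
#' off-diagonal elements. With `lambda = "ML"` (the default), `lambda` is
#' estimated jointly with the coefficients by maximizing the profile
#' likelihood over `[0, 1]` (deterministic grid pre-scan plus Brent).
#'
#' Reporting conventions: coefficient standard errors use the
#' unbiased-variance scaling `sigma2 * n / (n - p)` (the ML `sigma2` itself
#' is used for the likelihood and AIC); `R^2` compares the whitened residual
#' sum of squares against an intercept-only GLS fit under the *model's own*
#' `lambda`, making it a pure association measure; the parameter count is
#' `k = p + 1 (+1 if lambda is estimated)` and `AIC = 2k - 2 lnL`. Only AIC
#' *differences* within a battery matter for evidence ratios, and every
#' model in a battery shares the k convention, so the count convention
#' cancels there.
#'
#' @param data Data frame with one row per species, containing `species`
#'   and the model variables. Species absent from the tree (and vice versa)
#'   are dropped with a message; rows with missing model variables are
#'   dropped.
#' @param formula Model formula, e.g. `log_antennal_area ~ log_body_length`.
#'   An intercept is always included.
#' @param tree A `phylo` with branch lengths.
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @param species Name of the species-identifier column.
#' @return An object of class `pgls_fit`.
#' @examples
#' study <- synthetic_study(sim_config(n_species = 48, seed = 7))
#' dat <- add_log_traits(study$traits)
#' fit_pgls(dat, log_antennal_area ~ log_body_length, study$tree)
#' @export
fit_pgls <- function(data, formula, tree, lambda = "ML",
                     species = "species") {
  stopifnot(inherits(tree, "phylo"), inherits(formula, "formula"))
  data <- as.data.frame(data)
  if (!species %in% names(data)) {
    stop("column '", species, "' not found in `data`", call. = FALSE)
  }
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables not in `data`: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  sp <- as.character(data[[species]])
  if (anyDuplicated(sp)) stop("duplicate species in `data`", call. = FALSE)
  cc <- complete.cases(data[vars])
  used <- intersect(tree$tip.label, sp[cc])
  dropped <- length(union(tree$tip.label, sp)) - length(used)
  if (length(used) < 3L) {
    stop("fewer than 3 species shared between tree and complete data",
         call. = FALSE)
  }
  if (dropped > 0L) {
    message("fit_pgls: using ", length(used), " species (",
            dropped, " dropped in tree/data reconciliation)")
  }
  tr <- if (length(used) < ape::Ntip(tree)) {
    ape::keep.tip(tree, used)
  } else {
    tree
  }
  dat <- data[match(tr$tip.label, sp), , drop = FALSE]
  mf <- model.frame(formula, dat)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("too few species for the number of parameters",
                        call. = FALSE)
  V <- phylo_vcv(tr)
  if (identical(lambda, "ML")) {
    prof <- .lambda_profile(y, X, V)
    lam <- prof$lambda
    est_lambda <- TRUE
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
        lambda > 1) {
      stop("`lambda` must be \"ML\" or a single value in [0, 1]",
           call. = FALSE)
    }
    lam <- lambda
    est_lambda <- FALSE
  }
  Vl <- lambda_vcv(V, lam)
  g <- gls_profile_loglik(y, X, Vl)
  R <- chol(Vl)
  wX <- backsolve(R, X, transpose = TRUE)
  XtXinv <- chol2inv(chol(crossprod(wX)))
  se <- sqrt(diag(XtXinv) * g$sigma2 * n / (n - p))
  fitted <- drop(X %*% g$beta)
  resid <- setNames(y - fitted, tr$tip.label)
  r2 <- if (p == 1L && all(X[, 1L] == 1)) {
    0
  } else {
    g0 <- gls_profile_loglik(y, matrix(1, n, 1L), Vl)
    1 - g$sigma2 / g0$sigma2
  }
  k <- p + 1L + as.integer(est_lambda)
  structure(list(coefficients = g$beta,
                 se = setNames(se, names(g$beta)),
                 lambda = lam,
                 lambda_mode = if (est_lambda) "ML" else "fixed",
                 sigma2 = g$sigma2,
                 logLik = g$lnL,
                 k = k,
                 AIC = aic_of(g$lnL, k),
                 r.squared = r2,
                 residuals = resid,
                 fitted = setNames(fitted, tr$tip.label),
                 y = setNames(y, tr$tip.label),
                 n = n,
                 formula = formula,
                 capped = est_lambda && lam >= 1),
            class = "pgls_fit")
}

#' Akaike's information criterion from a log-likelihood
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of estimated parameters (coefficients, scale, and lambda
#'   when estimated).
#' @return `2 * k - 2 * lnL`.
#' @export
aic_of <- function(lnL, k) {
  stopifnot(is.numeric(lnL), is.numeric(k), k >= 1)
  2 * k - 2 * lnL
}

#' Evidence ratio of a model against a null model
#'
#' The relative likelihood `exp((AIC_null - AIC_model) / 2)`: how many times
#' more likely the model is than the null. Multiplicative across chained
#' comparisons, and 1 when the AICs are equal.
#'
#' @param aic_null AIC of the null (reference) model.
#' @param aic_model AIC of the candidate model.
#' @return The evidence ratio (positive real).
#' @examples
#' evidence_ratio(14.09, 12.38) # ~2.35
#' @export
evidence_ratio <- function(aic_null, aic_model) {
  stopifnot(is.finite(aic_null), is.finite(aic_model))
  exp((aic_null - aic_model) / 2)
}

#' Response-scale residuals of a PGLS fit
#'
#' Returns `y - X beta` keyed by species. Feeding these into [fit_lambda()]
#' gives the phylogenetic signal of a size-corrected trait (e.g. residual
#' antennal area after the allometric regression on body length).
#'
#' @param fit A `pgls_fit` object.
#' @return Named numeric vector of residuals.
#' @export
residuals_of <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$residuals
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat("  lambda =", format(x$lambda, digits = 4),
      paste0("(", x$lambda_mode, ")"),
      if (isTRUE(x$capped)) "[at upper bound 1]" else "", "\n")
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se)
  print(round(tab, 4))
  cat("  R^2 =", format(x$r.squared, digits = 3),
      " lnL =", format(x$logLik, digits = 6),
      " AIC =", format(x$AIC, digits = 6),
      " n =", x$n, "\n")
  invisible(x)
}

#' @rdname fit_pgls
#' @param x A `pgls_fit` object.
#' @param ... Unused.
#' @export
tidy.pgls_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  df <- x$n - length(est)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(stat),
                 p.value = 2 * pt(abs(unname(stat)), df, lower.tail = FALSE))
}

#' @rdname fit_pgls
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lambda_mode = x$lambda_mode,
                 sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
                 r.squared = x$r.squared, nobs = x$n, k = x$k)
}
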