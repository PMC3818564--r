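test_that("gls_profile_loglik reduces to OLS when V is the identity", {
  set.seed(51)
  n <- 20
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, -1) + rnorm(n)
  g <- gls_profile_loglik(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(g$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(g$sigma2, sum(ols$residuals^2) / n, tolerance = 1e-10)
})

test_that("gls_profile_loglik equals the multivariate-normal log-density", {
  tr <- random_tree(10, seed = 52)
  V <- phylo_vcv(tr)
  set.seed(53)
  y <- brownian_trait(tr, 1.3, root_state = 2)
  X <- cbind(`(Intercept)` = 1, x = rnorm(10))
  g <- gls_profile_loglik(y, X, V)
  # brute-force density at the returned parameters
  S <- g$sigma2 * V
  e <- as.numeric(y - X %*% g$beta)
  lnL_direct <- -0.5 * (10 * log(2 * pi) +
                          determinant(S, logarithm = TRUE)$modulus +
                          drop(e %*% solve(S, e)))
  expect_equal(g$lnL, as.numeric(lnL_direct), tolerance = 1e-8)
})

test_that("profile likelihood is invariant to global rescaling of V", {
  tr <- yule_tree(15, seed = 54)
  V <- phylo_vcv(tr)
  y <- brownian_trait(tr, 1, seed = 55)
  X <- matrix(1, 15, 1)
  g1 <- gls_profile_loglik(y, X, V)
  g10 <- gls_profile_loglik(y, X, 10 * V)
  expect_equal(g1$lnL, g10$lnL, tolerance = 1e-10)
  expect_equal(g1$beta, g10$beta, tolerance = 1e-10)
  expect_equal(g1$sigma2, 10 * g10$sigma2, tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  n <- 8
  X <- cbind(1, rep(2, n))
  expect_error(gls_profile_loglik(rnorm(n), X, diag(n)), "rank deficient")
  X1 <- cbind(1, 1:n)
  y <- X1 %*% c(1, 2)
  expect_error(gls_profile_loglik(y, X1, diag(n)), "perfect fit")
})

test_that("fit_lambda returns 0 on star trees (tie toward no signal)", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(56)
  y <- setNames(rnorm(6), star$tip.label)
  f <- fit_lambda(star, y)
  expect_identical(f$lambda, 0)
  expect_equal(f$LR, 0, tolerance = 1e-8)
})

test_that("fit_lambda maximizes the profile over a lambda grid", {
  for (seed in 1:10) {
    tr <- yule_tree(24, seed = seed + 200)
    set.seed(seed)
    y <- lambda_trait(tr, runif(1), 1)
    f <- fit_lambda(tr, y)
    V <- phylo_vcv(tr)
    X <- matrix(1, 24, 1)
    grid_ll <- vapply(seq(0, 1, length.out = 101), function(l) {
      gls_profile_loglik(y, X, lambda_vcv(V, l))$lnL
    }, numeric(1))
    expect_gte(f$lnL + 1e-8, max(grid_ll))
    expect_gte(f$lnL + 1e-10, f$lnL0)
    expect_true(f$p_value >= 0 && f$p_value <= 1)
  }
})

test_that("fit_lambda agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- yule_tree(48, seed = 57)
  y <- lambda_trait(tr, 0.6, 1, seed = 58)
  f <- fit_lambda(tr, y)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(f$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(f$lnL, ref$logL, tolerance = 1e-4)
})

test_that("lambda estimation error shrinks with tree size", {
  mse <- function(n_tips, lam, reps = 12) {
    est <- vapply(seq_len(reps), function(i) {
      tr <- yule_tree(n_tips)
      fit_lambda(tr, lambda_trait(tr, lam, 1))$lambda
    }, numeric(1))
    mean((est - lam)^2)
  }
  set.seed(59)
  for (lam in c(0, 0.5, 1)) {
    expect_lt(mse(256, lam), mse(64, lam) + 0.01)
  }
})

test_that("fit_lambda input validation", {
  tr <- yule_tree(10, seed = 60)
  expect_error(fit_lambda(tr, setNames(rep(1, 10), tr$tip.label)),
               "constant")
  expect_error(fit_lambda(tr, setNames(rnorm(9), tr$tip.label[-1])),
               "missing trait values")
})
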