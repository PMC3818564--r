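make_data <- function(tree, y, x = NULL) {
  d <- tibble::tibble(species = tree$tip.label, y = unname(y))
  if (!is.null(x)) d$x <- unname(x)
  d
}

test_that("PGLS on a star tree equals ordinary least squares", {
  star <- parse_newick(paste0("(", paste0("t", 1:12, ":1", collapse = ","),
                              ");"))
  set.seed(71)
  x <- setNames(rnorm(12), star$tip.label)
  y <- 1 + 0.5 * x + rnorm(12, sd = 0.3)
  dat <- make_data(star, y, x)
  fit <- fit_pgls(dat, y ~ x, star, lambda = 0)
  ref <- lm(y ~ x, data = dat)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(fit$r.squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("fixed-lambda PGLS matches the explicit matrix solution", {
  tr <- yule_tree(6, seed = 72)
  set.seed(73)
  x <- setNames(rnorm(6), tr$tip.label)
  y <- brownian_trait(tr, 1) + 0.8 * x
  fit <- fit_pgls(make_data(tr, y, x), y ~ x, tr, lambda = 1)
  V <- phylo_vcv(tr)
  X <- cbind(1, unname(x))
  beta_hand <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*%
                       as.numeric(y))
  expect_equal(unname(coef(fit)), as.numeric(beta_hand), tolerance = 1e-10)
})

test_that("lambda = 1 PGLS slope equals independent-contrasts regression", {
  for (seed in 1:5) {
    tr <- yule_tree(30, seed = seed + 300)
    set.seed(seed)
    x <- brownian_trait(tr, 1)
    y <- 2 + 1.4 * x + brownian_trait(tr, 0.2)
    fit <- fit_pgls(make_data(tr, y, x), y ~ x, tr, lambda = 1)
    picx <- ape::pic(x[tr$tip.label], tr)
    picy <- ape::pic(y[tr$tip.label], tr)
    slope_pic <- unname(coef(lm(picy ~ picx - 1)))
    expect_equal(unname(coef(fit)["x"]), slope_pic, tolerance = 1e-6)
  }
})

test_that("PGLS with ML lambda matches nlme::gls with corPagel", {
  skip_if_not_installed("nlme")
  tr <- yule_tree(40, seed = 74)
  set.seed(75)
  x <- brownian_trait(tr, 1)
  y <- 1 + 0.6 * x + lambda_trait(tr, 0.5, 0.3)
  dat <- make_data(tr, y, x)
  fit <- fit_pgls(dat, y ~ x, tr, lambda = 0.5)
  df <- data.frame(y = unname(y), x = unname(x),
                   species = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corPagel(0.5, tr, fixed = TRUE,
                                               form = ~species))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("whitened residuals satisfy the normal equations", {
  tr <- yule_tree(50, seed = 76)
  set.seed(77)
  x <- brownian_trait(tr, 1)
  y <- 0.3 + 2 * x + lambda_trait(tr, 0.7, 0.5)
  fit <- fit_pgls(make_data(tr, y, x), y ~ x, tr)
  e <- residuals_of(fit)
  Vl <- lambda_vcv(phylo_vcv(tr), fit$lambda)
  expect_lt(abs(sum(solve(Vl, unname(e[tr$tip.label])))), 1e-8)
  # reflecting y about the fitted line flips the residual sign
  dat2 <- make_data(tr, 2 * fit$fitted - fit$y, x)
  fit2 <- fit_pgls(dat2, y ~ x, tr, lambda = fit$lambda)
  expect_equal(unname(residuals_of(fit2)), -unname(e), tolerance = 1e-8)
})

test_that("AIC bookkeeping and evidence ratios are exact", {
  expect_equal(aic_of(0, 2), 4)
  expect_equal(aic_of(-5, 3), 16)
  expect_equal(evidence_ratio(3, 3), 1)
  # multiplicativity
  expect_equal(evidence_ratio(10, 6),
               evidence_ratio(10, 8) * evidence_ratio(8, 6))
  tr <- yule_tree(25, seed = 78)
  set.seed(79)
  x <- brownian_trait(tr, 1)
  y <- brownian_trait(tr, 1)
  dat <- make_data(tr, y, x)
  f0 <- fit_pgls(dat, y ~ 1, tr, lambda = 1)
  f1 <- fit_pgls(dat, y ~ x, tr, lambda = 1)
  expect_equal(f0$AIC, aic_of(f0$logLik, f0$k))
  # nested model with one extra ML coefficient cannot lose more than 2 AIC
  expect_lte(f1$AIC, f0$AIC + 2 + 1e-10)
  expect_gte(f1$logLik + 1e-10, f0$logLik)
})

test_that("slope recovery is unbiased under the generating model", {
  set.seed(80)
  for (lam in c(0, 1)) {
    slopes <- replicate(15, {
      tr <- yule_tree(64)
      x <- brownian_trait(tr, 1)
      y <- 1 + 2 * x + lambda_trait(tr, lam, 0.1)
      unname(coef(fit_pgls(make_data(tr, y, x), y ~ x, tr))["x"])
    })
    se <- sd(slopes) / sqrt(length(slopes))
    expect_lt(abs(mean(slopes) - 2), max(2 * se, 0.02))
  }
})

test_that("fit_pgls validates inputs", {
  tr <- yule_tree(10, seed = 81)
  dat <- make_data(tr, rnorm(10), rnorm(10))
  expect_error(fit_pgls(dat, y ~ missing_col, tr), "missing_col")
  expect_error(fit_pgls(dat, y ~ x, tr, lambda = 2), "ML")
  dat$species[2] <- dat$species[1]
  expect_error(fit_pgls(dat, y ~ x, tr), "duplicate")
})
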