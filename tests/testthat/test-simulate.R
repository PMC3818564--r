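test_that("yule_tree produces valid reproducible ultrametric trees", {
  two <- yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(two), 2L)
  expect_true(is_ultrametric(two))

  a <- yule_tree(126, seed = 99)
  b <- yule_tree(126, seed = 99)
  expect_identical(write_newick(a), write_newick(b))
  expect_true(ape::is.binary(a))
  expect_true(is_ultrametric(a))
  expect_error(yule_tree(1), ">= 2")
})

test_that("yule_tree depth matches the closed-form expectation", {
  set.seed(7)
  n <- 20
  depths <- replicate(500, max(tip_depths(yule_tree(n))))
  expected <- sum(1 / (2:n))
  mc_se <- sqrt(sum(1 / (2:n)^2) / 500)
  expect_lt(abs(mean(depths) - expected), 3 * mc_se)
})

test_that("brownian_trait has the Brownian contrast variance", {
  tr <- parse_newick("(A:1,B:1);")
  set.seed(11)
  diffs <- replicate(10000, {
    x <- brownian_trait(tr, sigma2 = 2)
    x[["A"]] - x[["B"]]
  })
  expect_equal(var(diffs), 2 * 2, tolerance = 0.05)
})

test_that("trait sample covariance converges to sigma2 * V(lambda)", {
  tr <- yule_tree(10, seed = 13)
  V <- phylo_vcv(tr)
  for (lam in c(0.5, 1)) {
    set.seed(17)
    X <- t(replicate(5000, if (lam == 1) brownian_trait(tr, 1.5)
                     else lambda_trait(tr, lam, 1.5)))
    S <- stats::cov(X)
    target <- 1.5 * lambda_vcv(V, lam)
    mc_bound <- 4 * sqrt((outer(diag(target), diag(target)) + target^2) /
                           5000)
    expect_true(all(abs(S - target) < mc_bound))
  }
})

test_that("lambda_trait limits behave correctly", {
  tr <- yule_tree(12, seed = 19)
  expect_equal(lambda_trait(tr, 1, 2, seed = 5),
               brownian_trait(tr, 2, seed = 5))
  set.seed(23)
  X <- t(replicate(4000, lambda_trait(tr, 0, 1)))
  S <- stats::cov(X)
  expect_equal(unname(diag(S)), unname(diag(phylo_vcv(tr))),
               tolerance = 0.15)
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 0.2 * max(diag(S)))
  expect_error(lambda_trait(tr, 1.2, 1), "\\[0, 1\\]")
})

test_that("binary generators fix the prevalence exactly and reproduce", {
  tr <- yule_tree(16, seed = 29)
  st <- threshold_binary(tr, 15, seed = 1)
  expect_identical(sum(st == 0L), 1L)
  expect_identical(threshold_binary(tr, 5, seed = 4),
                   threshold_binary(tr, 5, seed = 4))
  expect_identical(random_binary(tr, 5, seed = 4),
                   random_binary(tr, 5, seed = 4))
  expect_error(random_binary(tr, 16), "strictly between")
  expect_error(threshold_binary(tr, 0), "strictly between")
})

test_that("random_binary marginals are uniform", {
  labels <- paste0("t", 1:8)
  set.seed(31)
  freq <- rowMeans(replicate(10000, random_binary(labels, 3)))
  p <- 3 / 8
  expect_true(all(abs(freq - p) < 4 * sqrt(p * (1 - p) / 10000)))
})

test_that("threshold_binary clumps states on the phylogeny", {
  tr <- parse_newick(
    "(((A:1,B:1):1,(C:1,D:1):1):5,((E:1,F:1):1,(G:1,H:1):1):5);")
  one_clade <- function(st) {
    sum(st[c("A", "B", "C", "D")]) %in% c(0L, 4L)
  }
  set.seed(37)
  p_thresh <- mean(replicate(2000, one_clade(threshold_binary(tr, 4))))
  p_rand <- mean(replicate(2000, one_clade(random_binary(tr, 4))))
  expect_gt(p_thresh, p_rand)
})

test_that("synthetic_study satisfies the trait-table schema", {
  study <- synthetic_study(sim_config(seed = 41))
  tt <- study$traits
  expect_identical(nrow(tt), 126L)
  expect_identical(tt$species, study$tree$tip.label)
  expect_false(anyNA(tt))
  bins <- c("parasitoid", "egg_parasitoid", "specialist", "para_hemiptera",
            "para_sternorrhyncha", "para_other_hemiptera", "para_diptera",
            "para_lepidoptera", "para_coleoptera", "para_hymenoptera")
  for (b in bins) expect_true(all(tt[[b]] %in% c(0L, 1L)))
  expect_true(all(tt$host_species >= 1))
  expect_true(all(tt$host_orders >= 1))
  expect_true(all(tt$plant_genera >= 1))
  expect_true(all(tt$body_length_mm > 0))
  # hemiptera flag is the union of the suborder flags
  expect_identical(tt$para_hemiptera,
                   pmax(tt$para_sternorrhyncha, tt$para_other_hemiptera))
  # specialist follows the host-breadth rule
  expect_identical(tt$specialist,
                   as.integer(tt$parasitoid == 1L & tt$host_species < 10L &
                                tt$host_orders == 1L))
  # bit-identical under the same seed
  again <- synthetic_study(sim_config(seed = 41))
  expect_identical(tt, again$traits)
  expect_identical(write_newick(study$tree), write_newick(again$tree))
})

test_that("synthetic allometry recovers the generating slope", {
  cfg <- sim_config(n_species = 80, lambda_resid = 0, sigma2_resid = 1e-6,
                    seed = 43)
  study <- synthetic_study(cfg)
  dat <- add_log_traits(study$traits)
  fit <- fit_pgls(dat, log_antennal_area ~ log_body_length, study$tree)
  expect_equal(unname(coef(fit)["log_body_length"]), 1.7, tolerance = 1e-3)
})

test_that("host-species counts are right-skewed", {
  skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
  sk <- vapply(1:5, function(s) {
    skewness(synthetic_study(sim_config(seed = s))$traits$host_species)
  }, numeric(1))
  expect_true(all(sk > 0))
})
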