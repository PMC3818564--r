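# Fritz-Purvis D statistic for binary traits: the observed sum of
# sister-clade differences, scaled between its expectations under a
# phylogenetically random null (prevalence-preserving shuffle) and a
# Brownian-threshold null.

#' Observed sum of sister-clade differences for a binary trait
#'
#' Nodal values are estimated bottom-up as the unweighted mean of the two
#' daughter values (tips carry their 0/1 states; branch lengths are
#' ignored), and the observed change score is the sum over internal nodes of
#' the absolute difference between the two daughter values. Polytomies are
#' resolved with zero-length branches first.
#'
#' @param tree A rooted `phylo`.
#' @param states 0/1 vector named by tip label (non-constant).
#' @return The observed change score (non-negative real).
#' @export
d_observed <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- .check_binary_states(tree, states)
  tree <- resolve_polytomies(tree)
  drop(.d_multi(tree, matrix(as.numeric(states[tree$tip.label]))))
}

# Change scores for many state vectors at once. S is an n_tips x m matrix
# with rows in tip order of `tree` (binary tree required). Nodal averaging is
# linear in the tip states, so the postorder pass is vectorized across
# columns.
.d_multi <- function(tree, S) {
  n <- ape::Ntip(tree)
  m <- ncol(S)
  pr <- ape::reorder.phylo(tree, "postorder")
  vals <- matrix(0, n + tree$Nnode, m)
  vals[seq_len(n), ] <- S
  first <- integer(n + tree$Nnode)
  d <- numeric(m)
  e1 <- pr$edge[, 1L]
  e2 <- pr$edge[, 2L]
  for (k in seq_along(e1)) {
    p <- e1[k]
    ch <- e2[k]
    if (first[p] == 0L) {
      first[p] <- ch
    } else {
      a <- vals[first[p], ]
      b <- vals[ch, ]
      d <- d + abs(a - b)
      vals[p, ] <- (a + b) / 2
    }
  }
  d
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Scales the observed change score ([d_observed()]) between its simulated
#' expectations under two nulls with the observed prevalence: a uniformly
#' random assignment of states across tips (no signal, `D = 1`) and a
#' Brownian-threshold model (`D = 0`). Values below 0 indicate clumping
#' stronger than the Brownian expectation. `p_random` is the proportion of
#' random-null scores at or below the observed score (departure from
#' `D = 1`); `p_brownian` is the proportion of Brownian-null scores at or
#' above it (departure from `D = 0`). Both are raw tail proportions without
#' a +1 correction.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param states 0/1 vector named by tip label (non-constant).
#' @param n_sim Number of simulations per null (at least 100).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `d_fit` with elements `D`, `d_obs`,
#'   `mean_random`, `mean_brownian`, `p_random`, `p_brownian`, `n_sim`,
#'   `n`, `n_ones`, and `seed`.
#' @examples
#' set.seed(42)
#' tr <- yule_tree(64)
#' st <- threshold_binary(tr, 16)
#' fit_d(tr, st, n_sim = 200)
#' @export
fit_d <- function(tree, states, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  states <- .check_binary_states(tree, states)
  if (!is.numeric(n_sim) || n_sim < 100) {
    stop("`n_sim` must be at least 100", call. = FALSE)
  }
  n_sim <- as.integer(n_sim)
  tree <- resolve_polytomies(tree)
  n <- ape::Ntip(tree)
  n_ones <- sum(states)
  if (!is.null(seed)) set.seed(seed)
  d_obs <- drop(.d_multi(tree, matrix(as.numeric(states[tree$tip.label]))))
  # random null: prevalence-preserving shuffles
  S_rand <- vapply(seq_len(n_sim), function(j) {
    v <- numeric(n)
    v[sample.int(n, n_ones)] <- 1
    v
  }, numeric(n))
  # Brownian-threshold null: one liability per simulation, shared Cholesky
  V <- phylo_vcv(tree)
  R <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-10 * mean(diag(V)), n))
  })
  liab <- crossprod(R, matrix(rnorm(n * n_sim), n, n_sim))
  S_brown <- apply(liab, 2L, function(x) {
    v <- numeric(n)
    v[order(x, decreasing = TRUE)[seq_len(n_ones)]] <- 1
    v
  })
  d_rand <- .d_multi(tree, S_rand)
  d_brown <- .d_multi(tree, S_brown)
  mr <- mean(d_rand)
  mb <- mean(d_brown)
  if (abs(mr - mb) < 1e-12) {
    stop("degenerate scaling: the random and Brownian null means of the ",
         "change score coincide", call. = FALSE)
  }
  structure(list(D = (d_obs - mb) / (mr - mb),
                 d_obs = d_obs,
                 mean_random = mr,
                 mean_brownian = mb,
                 p_random = mean(d_rand <= d_obs),
                 p_brownian = mean(d_brown >= d_obs),
                 n_sim = n_sim,
                 n = n,
                 n_ones = n_ones,
                 seed = seed),
            class = "d_fit")
}

#' @export
print.d_fit <- function(x, ...) {
  cat("Fritz-Purvis D:", format(x$D, digits = 4), "\n")
  cat("  observed change score:", format(x$d_obs, digits = 4),
      " (random null mean ", format(x$mean_random, digits = 4),
      ", Brownian null mean ", format(x$mean_brownian, digits = 4), ")\n",
      sep = "")
  cat("  p (vs D = 1, random):", format.pval(x$p_random, digits = 3),
      "  p (vs D = 0, Brownian):", format.pval(x$p_brownian, digits = 3),
      "\n")
  cat("  n =", x$n, " ones =", x$n_ones, " n_sim =", x$n_sim, "\n")
  invisible(x)
}

#' @rdname fit_d
#' @param x A `d_fit` object.
#' @param ... Unused.
#' @export
tidy.d_fit <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D, p.random = x$p_random,
                 p.brownian = x$p_brownian)
}

#' @rdname fit_d
#' @export
glance.d_fit <- function(x, ...) {
  tibble::tibble(D = x$D, d_obs = x$d_obs, mean_random = x$mean_random,
                 mean_brownian = x$mean_brownian, p.random = x$p_random,
                 p.brownian = x$p_brownian, n_sim = x$n_sim, nobs = x$n,
                 n_ones = x$n_ones)
}
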