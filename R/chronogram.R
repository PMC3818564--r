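# Penalized-likelihood ultrametricization (rate smoothing sensu Sanderson):
# node ages and per-edge rates maximize a Poisson-type branch likelihood
# penalized for rate changes between adjacent edges. Delegated to
# ape::chronos(model = "correlated") with the smoothing weight fixed by the
# caller (no cross-validation).

#' Resolve polytomies to a binary tree
#'
#' Multifurcations are resolved deterministically (in tip-order grouping)
#' with zero-length edges, which leaves all path lengths unchanged; a warning
#' records that the resolution is arbitrary. Algorithms that assume binary
#' trees (penalized likelihood, Fitch counting, nodal averaging for D) call
#' this internally.
#'
#' @param tree A `phylo` object.
#' @param warn Emit a warning when a resolution actually happens.
#' @return A binary `phylo`.
#' @export
resolve_polytomies <- function(tree, warn = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  if (warn) {
    warning("tree contains polytomies; resolved arbitrarily with ",
            "zero-length branches", call. = FALSE)
  }
  ape::multi2di(tree, random = FALSE)
}

#' Make a tree ultrametric by penalized-likelihood rate smoothing
#'
#' Estimates relative node ages (root fixed at 1, tips at 0) and per-edge
#' substitution rates by maximizing the penalized likelihood of the observed
#' branch lengths, with a roughness penalty of weight `smoothing` on rate
#' differences between ancestor and descendant edges. Zero or missing branch
#' lengths are replaced by `1e-8` times the tree height so the objective
#' stays finite and downstream covariance matrices stay positive definite.
#'
#' Downstream signal and regression analyses are invariant to a global
#' rescaling of the chronogram, so the arbitrary root age of 1 is harmless.
#'
#' @param tree A rooted `phylo` with branch lengths in expected substitutions
#'   (polytomies are resolved first, with a warning).
#' @param smoothing Positive penalty weight on rate roughness. Larger values
#'   pull the solution toward a strict clock.
#' @param tol Relative tolerance used to verify the result is ultrametric.
#' @return An object of class `chronogram`: a list with elements `tree` (the
#'   ultrametric `phylo`), `rates` (per-edge rate estimates), `objective`
#'   (achieved penalized log-likelihood), and `smoothing`.
#' @export
ultrametricize_pl <- function(tree, smoothing = 10, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(smoothing) || length(smoothing) != 1L || smoothing <= 0) {
    stop("`smoothing` must be a single positive number", call. = FALSE)
  }
  tree <- resolve_polytomies(tree)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  h <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * h
  el <- tree$edge.length
  el[is.na(el) | el <= 0] <- eps
  tree$edge.length <- el
  if (ape::Ntip(tree) == 2L) {
    # the constraints force both tips to age 0 and the root to age 1;
    # only the two rates remain free
    x <- tree$edge.length
    obj <- function(lr) {
      r <- exp(lr)
      sum(x * log(r) - r) - smoothing * (r[1] - r[2])^2 / 2
    }
    opt <- stats::optim(log(x), obj, control = list(fnscale = -1))
    out <- tree
    out$edge.length <- c(1, 1)
    return(structure(list(tree = out, rates = exp(opt$par),
                          objective = opt$value, smoothing = smoothing),
                     class = "chronogram"))
  }
  chr <- suppressWarnings(suppressMessages(
    ape::chronos(tree, lambda = smoothing, model = "correlated",
                 quiet = TRUE)
  ))
  rates <- attr(chr, "rates")
  objective <- attr(chr, "ploglik")
  out <- list(edge = chr$edge, edge.length = chr$edge.length,
              Nnode = chr$Nnode, tip.label = chr$tip.label)
  class(out) <- "phylo"
  attr(out, "order") <- attr(chr, "order")
  if (!is_ultrametric(out, rel_tol = tol)) {
    stop("penalized-likelihood smoothing failed to produce an ultrametric ",
         "tree (best objective ", format(objective), ")", call. = FALSE)
  }
  structure(list(tree = out, rates = as.numeric(rates),
                 objective = as.numeric(objective), smoothing = smoothing),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("Penalized-likelihood chronogram\n")
  cat("  tips:", ape::Ntip(x$tree), "  smoothing:", x$smoothing, "\n")
  cat("  objective:", format(x$objective), "\n")
  cat("  rate range: [", format(min(x$rates)), ",",
      format(max(x$rates)), "]\n")
  invisible(x)
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured back from the tips (tips at 0, root at tree height).
#'
#' @param x A `chronogram` or an ultrametric `phylo`.
#' @return Numeric vector of ages for all nodes (tips first, then internal
#'   nodes, in ape numbering).
#' @export
node_ages <- function(x) {
  tree <- if (inherits(x, "chronogram")) x$tree else x
  stopifnot(inherits(tree, "phylo"))
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}
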