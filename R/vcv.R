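#' Phylogenetic variance-covariance matrix
#'
#' Expected trait covariance among tips under Brownian motion: entry (i, j)
#' is the path length from the root to the most recent common ancestor of
#' tips i and j; the diagonal holds the root-to-tip depths. On an ultrametric
#' tree all diagonal entries are equal.
#'
#' @param tree A `phylo` object with branch lengths (polytomies allowed).
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  ape::vcv(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal elements of `V` by `lambda`, leaving the
#' diagonal unchanged. `lambda = 1` returns `V`; `lambda = 0` returns the
#' diagonal matrix of tip depths (phylogenetic independence).
#'
#' @param V Symmetric covariance matrix (from [phylo_vcv()]).
#' @param lambda Non-negative multiplier, typically in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_vcv <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}
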