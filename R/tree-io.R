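#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. Accepts quoted labels
#' and internal-node labels, ignores square-bracket comments, and preserves
#' polytomies. Trees without any `:` tokens are returned without branch
#' lengths (`edge.length` absent, not zero).
#'
#' @param text A single Newick string terminated by `";"`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tip_depths(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty Newick string", call. = FALSE)
  # strip comments before the balance check
  bare <- gsub("\\[[^]]*\\]", "", txt)
  chars <- strsplit(bare, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("unbalanced parentheses: unmatched ')' at position ",
         which(depth < 0)[1], call. = FALSE)
  }
  if (depth[length(depth)] != 0) {
    stop("unbalanced parentheses: ", depth[length(depth)],
         " '(' left open", call. = FALSE)
  }
  if (!grepl(";\\s*$", bare)) {
    stop("Newick string must be terminated by ';'", call. = FALSE)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick string", call. = FALSE)
  tree$tip.label <- trimws(gsub("^'(.*)'$", "\\1", tree$tip.label))
  if (any(!nzchar(tree$tip.label))) {
    stop("tree contains empty tip labels", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tree
}

#' Serialize a phylogeny to Newick
#'
#' Round-trip companion to [parse_newick()]: `parse_newick(write_newick(t))`
#' reproduces topology, labels, and branch lengths to print precision.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root-to-tip path lengths
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of root-to-tip depths, in tip order.
#' @export
tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  setNames(d, tree$tip.label)
}

#' Test whether a tree is ultrametric
#'
#' A tree is treated as ultrametric when the relative spread of root-to-tip
#' depths, `(max - min) / max`, does not exceed `rel_tol`.
#'
#' @inheritParams tip_depths
#' @param rel_tol Relative tolerance on tip-depth spread.
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) / max(d) <= rel_tol
}
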