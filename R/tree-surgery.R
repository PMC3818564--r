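# Tree-assembly rules used when merging published phylogenies that differ in
# taxon sampling and branch-length information.

#' Prune a tree to a set of tips
#'
#' Retains exactly the tips in `keep`; unbranched internal nodes created by
#' the pruning are suppressed with their branch lengths summed, so the
#' root-to-tip depth of every retained tip is unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least two).
#' @return The pruned `phylo`.
#' @export
prune_to <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) {
    stop("`keep` must contain at least two tips", call. = FALSE)
  }
  ape::keep.tip(tree, keep)
}

#' Insert a sibling tip halfway along an existing pendant branch
#'
#' Implements the convention for congeners absent from a backbone phylogeny:
#' the new species is assumed to be the sibling of an existing tip, with the
#' branching point halfway along that tip's pendant branch. Both siblings end
#' up at the same depth, and all other depths are unchanged; an ultrametric
#' input stays ultrametric.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param existing_tip Label of the tip whose pendant branch is bisected.
#' @param new_tip Label of the tip to insert (must not already occur).
#' @return The augmented `phylo`.
#' @export
attach_sibling_halfway <- function(tree, existing_tip, new_tip) {
  stopifnot(inherits(tree, "phylo"))
  i <- match(existing_tip, tree$tip.label)
  if (is.na(i)) stop("tip not in tree: ", existing_tip, call. = FALSE)
  if (new_tip %in% tree$tip.label) {
    stop("tip already present: ", new_tip, call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; cannot bisect", call. = FALSE)
  }
  b <- tree$edge.length[tree$edge[, 2] == i]
  if (is.na(b) || b <= 0) {
    stop("pendant branch of '", existing_tip,
         "' has no positive length; cannot bisect", call. = FALSE)
  }
  phytools::bind.tip(tree, as.character(new_tip),
                     edge.length = b / 2, where = i, position = b / 2)
}

#' Graft a subtree onto a backbone with branch-length rescaling
#'
#' Replaces the pendant branch of a reference species `ref` in `backbone`
#' with an intrageneric `subtree` that also contains `ref`. All subtree
#' branch lengths are multiplied by `s = d_back / d_sub`, where `d_back` is
#' the length of `ref`'s pendant branch in the backbone and `d_sub` the
#' root-to-`ref` distance in the subtree, so that the depth of `ref` is
#' exactly preserved and the remaining subtree species are placed on the
#' backbone's branch-length scale.
#'
#' Subtrees without branch lengths are refused: apply
#' [set_equal_branch_lengths()] first, so the equal-lengths convention is an
#' explicit, auditable step.
#'
#' @param backbone A `phylo` with branch lengths containing tip `ref`.
#' @param subtree A `phylo` with branch lengths containing tip `ref`.
#' @param ref Tip label shared by both trees, used as the scale reference.
#' @return The combined `phylo`.
#' @export
graft_rescaled <- function(backbone, subtree, ref) {
  stopifnot(inherits(backbone, "phylo"), inherits(subtree, "phylo"))
  if (!ref %in% backbone$tip.label) {
    stop("reference tip '", ref, "' not in backbone", call. = FALSE)
  }
  if (ape::Ntip(subtree) == 1L) {
    if (!identical(subtree$tip.label, as.character(ref))) {
      stop("reference tip '", ref, "' not in subtree", call. = FALSE)
    }
    return(backbone)
  }
  if (!ref %in% subtree$tip.label) {
    stop("reference tip '", ref, "' not in subtree", call. = FALSE)
  }
  clash <- intersect(setdiff(subtree$tip.label, ref), backbone$tip.label)
  if (length(clash)) {
    stop("subtree tips already in backbone: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  if (is.null(subtree$edge.length) || anyNA(subtree$edge.length)) {
    stop("subtree has no branch lengths; apply set_equal_branch_lengths() ",
         "before grafting", call. = FALSE)
  }
  d_sub <- unname(tip_depths(subtree)[ref])
  if (d_sub <= 0) stop("root-to-'", ref, "' distance in subtree is zero",
                       call. = FALSE)
  tip_i <- match(ref, backbone$tip.label)
  edge_i <- which(backbone$edge[, 2] == tip_i)
  d_back <- backbone$edge.length[edge_i]
  if (is.na(d_back) || d_back <= 0) {
    stop("pendant branch of '", ref, "' in backbone has no positive length",
         call. = FALSE)
  }
  sub <- subtree
  sub$edge.length <- sub$edge.length * (d_back / d_sub)
  attach_node <- backbone$edge[edge_i, 1]
  tmp <- backbone
  tmp$tip.label[tip_i] <- ".chalcomp.graft.tmp."
  out <- ape::bind.tree(tmp, sub, where = attach_node, position = 0)
  ape::drop.tip(out, ".chalcomp.graft.tmp.")
}

#' Assign one common length to every branch
#'
#' The convention for source phylogenies published without branch-length
#' information: every edge is given the same length before grafting or
#' ultrametricization.
#'
#' @param tree A `phylo` object.
#' @param value Positive branch length to assign.
#' @return The `phylo` with constant branch lengths (topology unchanged).
#' @export
set_equal_branch_lengths <- function(tree, value = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    stop("`value` must be a single positive number", call. = FALSE)
  }
  tree$edge.length <- rep(as.numeric(value), nrow(tree$edge))
  tree
}
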