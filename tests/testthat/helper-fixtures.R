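# Shared fixtures and independent oracles used across test files.

tree_abc <- function() parse_newick("((A:1,B:1):1,C:2);")

balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# random non-ultrametric tree via ape (independent code path from yule_tree)
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# Oracle: phylogenetic covariance by per-pair MRCA path summation.
vcv_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  m <- ape::mrca(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) V[i, j] <- depth[m[i, j]]
  }
  diag(V) <- depth[seq_len(n)]
  V
}

# Oracle: change score by direct recursion on the edge matrix.
d_oracle <- function(tree, states) {
  n <- ape::Ntip(tree)
  states <- states[tree$tip.label]
  total <- 0
  value <- function(node) {
    if (node <= n) return(as.numeric(states[[node]]))
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    v <- vapply(kids, value, numeric(1))
    total <<- total + abs(v[1] - v[2])
    mean(v)
  }
  value(n + 1L)
  total
}

# Oracle: Fitch length by exhaustive minimization over internal assignments.
fitch_oracle <- function(tree, states) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  states <- as.integer(states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^m - 1)) {
    internal <- as.integer(intToBits(code)[seq_len(m)])
    full <- c(states, internal)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Bipartition set of a tree as a canonical character vector.
bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- vapply(pp, function(idx) {
    paste(sort(labs[idx]), collapse = "|")
  }, character(1))
  sort(unique(sets))
}
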