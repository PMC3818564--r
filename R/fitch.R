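#' Minimum number of state changes under Fitch parsimony
#'
#' Counts the minimum number of binary state changes required to explain the
#' tip states on the tree (the Fitch parsimony length), used to count
#' independent origins of a host-use trait. Polytomies are resolved with
#' zero-length branches first (which cannot decrease the count). The count is
#' accumulated by the standard union/intersection pass; an ambiguous root
#' state does not add a change. A constant trait gives 0.
#'
#' @param tree A rooted `phylo` object.
#' @param states Vector of 0/1 states (numeric or logical), named by tip
#'   label, covering every tip.
#' @return Integer parsimony length.
#' @export
count_origins_fitch <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- .check_binary_states(tree, states, allow_constant = TRUE)
  tree <- resolve_polytomies(tree)
  n <- ape::Ntip(tree)
  pr <- ape::reorder.phylo(tree, "postorder")
  sets <- integer(n + tree$Nnode)
  sets[seq_len(n)] <- ifelse(states[tree$tip.label] == 0, 1L, 2L)
  changes <- 0L
  seen <- integer(n + tree$Nnode) # first-child state set per parent
  for (k in seq_len(nrow(pr$edge))) {
    p <- pr$edge[k, 1L]
    ch <- pr$edge[k, 2L]
    if (seen[p] == 0L) {
      seen[p] <- sets[ch]
    } else {
      s <- bitwAnd(seen[p], sets[ch])
      if (s == 0L) {
        s <- bitwOr(seen[p], sets[ch])
        changes <- changes + 1L
      }
      sets[p] <- s
      seen[p] <- s
    }
  }
  changes
}

# Validate and coerce tip states to a named 0/1 vector in tip order.
.check_binary_states <- function(tree, states, allow_constant = FALSE) {
  if (is.logical(states)) states <- as.integer(states)
  if (is.null(names(states))) {
    if (length(states) != ape::Ntip(tree)) {
      stop("`states` must be named by tip label or match the number of tips",
           call. = FALSE)
    }
    names(states) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("missing states for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  states <- states[tree$tip.label]
  if (!all(states %in% c(0, 1))) {
    stop("`states` must contain only 0 and 1", call. = FALSE)
  }
  if (!allow_constant && length(unique(states)) < 2L) {
    stop("`states` is constant across tips", call. = FALSE)
  }
  states
}
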