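test_that("prune_to keeps requested tips and preserves their depths", {
  pruned <- prune_to(tree_abc(), c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  expect_equal(unname(tip_depths(pruned)[c("A", "C")]), c(2, 2))

  all_kept <- prune_to(tree_abc(), c("A", "B", "C"))
  expect_identical(bipartitions(all_kept), bipartitions(tree_abc()))
  expect_equal(tip_depths(all_kept), tip_depths(tree_abc()))

  big <- yule_tree(64, seed = 5)
  keep <- sample(big$tip.label, 10)
  sub <- prune_to(big, keep)
  expect_equal(tip_depths(sub)[sort(keep)], tip_depths(big)[sort(keep)],
               tolerance = 1e-9)

  expect_error(prune_to(tree_abc(), c("A", "Z")), "Z")
  expect_error(prune_to(tree_abc(), "A"), "two tips")
})

test_that("attach_sibling_halfway bisects the pendant branch", {
  tr <- parse_newick("(A:4,C:4);")
  out <- attach_sibling_halfway(tr, "A", "B")
  d <- tip_depths(out)
  expect_equal(unname(d[c("A", "B", "C")]), c(4, 4, 4))
  b_edge <- out$edge.length[out$edge[, 2] == match("B", out$tip.label)]
  expect_equal(b_edge, 2)
  expect_equal(ape::Ntip(out), 3L)
  expect_true(is_ultrametric(out))

  tr1 <- parse_newick("(A:1,C:1);")
  out1 <- attach_sibling_halfway(tr1, "A", "B")
  expect_equal(unname(tip_depths(out1)["B"]), 1)
  expect_equal(out1$edge.length[out1$edge[, 2] ==
                                  match("B", out1$tip.label)], 0.5)

  topo <- parse_newick("((A,B),(C,D));")
  expect_error(attach_sibling_halfway(topo, "A", "E"), "branch length")
  expect_error(attach_sibling_halfway(tr, "A", "C"), "already present")
})

test_that("graft_rescaled puts subtree tips on the backbone scale", {
  backbone <- parse_newick("((R:6,X:4):1,Y:5);")
  subtree <- parse_newick("((R:1.5,S:1.5):1.5,T:2);") # root-to-R = 3
  out <- graft_rescaled(backbone, subtree, "R")
  d <- tip_depths(out)
  # scale factor 2: depth(R) preserved exactly at 7
  expect_identical(unname(d["R"]), 7)
  # other genus tips: attachment depth 1 + 2 x subtree depth
  expect_equal(unname(d["S"]), 1 + 2 * 3)
  expect_equal(unname(d["T"]), 1 + 2 * 2)
  expect_equal(unname(d[c("X", "Y")]), c(5, 5))

  singleton <- parse_newick("(R:9);")
  expect_identical(graft_rescaled(backbone, singleton, "R"), backbone)

  expect_error(graft_rescaled(backbone, subtree, "Q"), "not in backbone")
  clash <- parse_newick("((R:1,X:1):1,T:2);")
  expect_error(graft_rescaled(backbone, clash, "R"), "already in backbone")
  bare <- parse_newick("((R,S),T);")
  expect_error(graft_rescaled(backbone, bare, "R"),
               "set_equal_branch_lengths")
})

test_that("graft_rescaled depth oracle holds on simulated trees", {
  backbone <- yule_tree(20, seed = 21)
  ref <- backbone$tip.label[7]
  genus <- yule_tree(5, seed = 22)
  genus$tip.label <- c(ref, paste0("g", 1:4))
  out <- graft_rescaled(backbone, genus, ref)
  expect_equal(unname(tip_depths(out)[ref]),
               unname(tip_depths(backbone)[ref]), tolerance = 1e-12)
  # independent path summation: attachment depth + scaled subtree depths
  i <- match(ref, backbone$tip.label)
  d_back <- backbone$edge.length[backbone$edge[, 2] == i]
  attach_depth <- unname(tip_depths(backbone)[ref]) - d_back
  s <- d_back / unname(tip_depths(genus)[ref])
  expect_equal(unname(tip_depths(out)[paste0("g", 1:4)]),
               unname(attach_depth + s * tip_depths(genus)[paste0("g", 1:4)]),
               tolerance = 1e-10)
})

test_that("set_equal_branch_lengths is uniform and idempotent", {
  topo <- parse_newick("((A,B),(C,D));")
  eq <- set_equal_branch_lengths(topo, 1)
  expect_equal(eq$edge.length, rep(1, 6))
  expect_identical(set_equal_branch_lengths(eq, 1)$edge.length,
                   eq$edge.length)

  cat4 <- set_equal_branch_lengths(parse_newick("(((A,B),C),D);"), 1)
  expect_equal(sort(unname(tip_depths(cat4))), c(1, 2, 3, 3))
  expect_error(set_equal_branch_lengths(topo, 0), "positive")
})
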