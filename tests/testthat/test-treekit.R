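test_that("pruning preserves root-to-tip depths and handles identity", {
  tr <- tree3()
  pr <- prune_tree(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  d <- ape::node.depth.edgelength(pr)[seq_len(2)]
  expect_equal(unname(d), c(2, 2))  # A's 1+1 summed, C unchanged
  # identity prune
  pr_all <- prune_tree(tr, c("A", "B", "C"))
  expect_true(ape::all.equal.phylo(pr_all, tr, use.edge.length = TRUE))
  expect_error(prune_tree(tr, c("A", "Z")), "Z")
})

test_that("find_polytomies reports every node of degree > 2", {
  expect_equal(nrow(find_polytomies(tree3())), 0)
  star <- star_tree(5)
  p <- find_polytomies(star)
  expect_equal(nrow(p), 1)
  expect_equal(p$degree, 5)
  two_tri <- ape::read.tree(text = "((A:1,B:1,C:1):1,(D:1,E:1,F:1):1);")
  p2 <- find_polytomies(two_tri)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$degree, c(3, 3))
})

test_that("resolution returns binary ultrametric trees preserving tips and ages", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1,D:1):1,(E:1.5,F:1.5):0.5);")
  ens <- resolve_polytomies(tr, 20, seed = 11)
  expect_length(ens, 20)
  expect_length(attr(ens, "seeds"), 20)
  for (t2 in ens) {
    expect_true(ape::is.binary(t2))
    expect_true(is_ultrametric(t2, 1e-8))
    expect_setequal(t2$tip.label, tr$tip.label)
    expect_equal(tree_height(t2), 2)
    # polytomy of degree 4 gains exactly 2 new internal nodes
    expect_equal(t2$Nnode, tr$Nnode + 2)
    # age of the pre-existing E,F ancestor preserved
    mrca_ef <- ape::getMRCA(t2, c("E", "F"))
    age_ef <- tree_height(t2) - ape::node.depth.edgelength(t2)[mrca_ef]
    expect_equal(age_ef, 1.5, tolerance = 1e-9)
    # inserted ages strictly inside (child age, polytomy age): no negative
    # branches anywhere
    expect_true(all(t2$edge.length >= 0))
    mrca_abcd <- ape::getMRCA(t2, c("A", "B", "C", "D"))
    age_abcd <- tree_height(t2) - ape::node.depth.edgelength(t2)[mrca_abcd]
    expect_equal(age_abcd, 1, tolerance = 1e-9)
  }
})

test_that("binary input yields identical copies; bad inputs error", {
  tr <- tree3()
  ens <- resolve_polytomies(tr, 10, seed = 3)
  expect_length(ens, 10)
  for (t2 in ens) expect_identical(ape::write.tree(t2), ape::write.tree(tr))
  expect_error(resolve_polytomies(tr, 0), "n_trees")
  bad <- ape::read.tree(text = "((A:1,B:3):1,C:2);")
  expect_error(resolve_polytomies(bad, 2), "ultrametric")
})

test_that("same seed gives bit-identical Newick output", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1,D:1):1,E:2);")
  e1 <- resolve_polytomies(tr, 5, seed = 42)
  e2 <- resolve_polytomies(tr, 5, seed = 42)
  e3 <- resolve_polytomies(tr, 5, seed = 43)
  expect_identical(vapply(e1, ape::write.tree, character(1)),
                   vapply(e2, ape::write.tree, character(1)))
  expect_false(identical(vapply(e1, ape::write.tree, character(1)),
                         vapply(e3, ape::write.tree, character(1))))
})

test_that("newick i/o round-trips single and multi-tree files", {
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- tree3()
  write_newick(tr, f)
  expect_true(ape::all.equal.phylo(read_newick(f), tr))
  ens <- resolve_polytomies(star_tree(4), 3, seed = 1)
  write_newick(ens, f)
  back <- read_newick(f)
  expect_s3_class(back, "multiPhylo")
  expect_length(back, 3)
})

test_that("collapse_to_polytomies preserves tip depths and creates polytomies", {
  set.seed(5)
  tr <- ape::rcoal(30)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  set.seed(6)
  poly <- collapse_to_polytomies(tr, 0.4)
  expect_gt(nrow(find_polytomies(poly)), 0)
  expect_setequal(poly$tip.label, tr$tip.label)
  expect_true(is_ultrametric(poly, 1e-8))
  expect_equal(tree_height(poly), tree_height(tr), tolerance = 1e-10)
  expect_identical(collapse_to_polytomies(tr, 0), tr)
})

test_that("validate_phylogeny reports zero-length terminal branches", {
  tr <- ape::read.tree(text = "((A:0,B:0):2,C:2);")
  expect_message(validate_phylogeny(tr), "zero-length terminal")
})
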