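test_that("read_newick parses valid trees and rejects malformed input", {
  tr <- read_newick("(A:1,B:1):0;", units = "subs/site")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sum(tr$edge.length), 2)
  expect_equal(tree_units(tr), "subs/site")

  expect_error(read_newick("(A:1,A:1);"), "duplicate tip")
  expect_error(read_newick("(A:1,B);"), "missing|non-finite")
  expect_error(read_newick("((A:1,B:1):1;"), "parse")
})

test_that("newick write/read round-trips topology and branch lengths", {
  for (seed in 1:10) {
    tr <- random_time_tree(sample(3:12, 1), seed = seed)
    tr2 <- read_newick(write_newick(tr), units = "Myr")
    expect_setequal(tr2$tip.label, tr$tip.label)
    d1 <- tip_depths(tr)
    expect_equal(tip_depths(tr2)[names(d1)], d1, tolerance = 1e-9)
    expect_equal(sum(tr2$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("pruning keeps retained-tip depths and collapses unifurcations", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_tips(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(unname(tip_depths(pr)[c("A", "C")]), c(2, 2))

  expect_equal(write_newick(prune_to_tips(tr, c("A", "B", "C"))),
               write_newick(tr))
  expect_error(prune_to_tips(tr, "Z"), "unknown tip")
  expect_error(prune_to_tips(tr, character(0)), "empty")

  # depth invariance on random trees and random subsets
  set.seed(42)
  for (i in 1:25) {
    tr <- random_time_tree(sample(4:15, 1), seed = 100 + i)
    keep <- sample(tr$tip.label, sample(2:(ape::Ntip(tr) - 1), 1))
    d0 <- tip_depths(tr)[keep]
    expect_equal(tip_depths(prune_to_tips(tr, keep))[keep], d0,
                 tolerance = 1e-9)
  }
})

test_that("crown-age calibration rescales branches and composes multiplicatively", {
  tr <- random_time_tree(6, seed = 3, crown = 1)
  cal <- calibrate_relative_tree(tr, 3.5)
  expect_equal(tree_height(cal), 3.5, tolerance = 1e-9)
  expect_equal(cal$edge.length, tr$edge.length * 3.5, tolerance = 1e-12)
  expect_equal(tree_units(cal), "Myr")

  # crown age equal to current height is the identity
  same <- calibrate_relative_tree(tr, tree_height(tr))
  expect_equal(same$edge.length, tr$edge.length, tolerance = 1e-12)

  # calibrate twice = calibrate once with the product
  two <- calibrate_relative_tree(calibrate_relative_tree(tr, 2), 2 * tree_height(tr))
  one <- calibrate_relative_tree(tr, 2 * tree_height(tr))
  expect_equal(two$edge.length, one$edge.length, tolerance = 1e-9)

  expect_error(calibrate_relative_tree(tr, -1), "positive")
  zero <- tr; zero$edge.length[] <- 0
  expect_error(calibrate_relative_tree(zero, 1), "zero root depth")
})

test_that("grafting a subtree preserves tip depths and counts", {
  sp <- simulate_bd_tree(26, 0.3, 0.1, 10, seed = 5)
  sub <- calibrate_relative_tree(simulate_coalescent_tree(53, seed = 6), 0.2)
  sub$tip.label <- sprintf("ind%02d", 1:53)
  # graft onto the tip with the longest stem
  stems <- sp$edge.length[match(1:26, sp$edge[, 2])]
  tip <- sp$tip.label[which.max(stems)]
  comb <- graft_subtree(sp, tip, sub)
  expect_equal(ape::Ntip(comb), 26 - 1 + 53)
  expect_true(is_ultrametric_tree(comb))
  expect_equal(tree_height(comb), tree_height(sp), tolerance = 1e-9)

  # graft then prune back to one subtree tip restores the species-tree depth
  pruned <- prune_to_tips(comb, c(setdiff(sp$tip.label, tip), "ind01"))
  expect_equal(unname(tree_height(pruned)), unname(tree_height(sp)),
               tolerance = 1e-9)

  # a 1-tip subtree of age 0 only relabels
  single <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           edge.length = 0, tip.label = "X", Nnode = 1L),
                      class = "phylo")
  relab <- graft_subtree(sp, tip, set_tree_units(single, "Myr"))
  expect_equal(ape::Ntip(relab), 26)
  expect_true("X" %in% relab$tip.label)

  # subtree older than the stem fails
  tall <- calibrate_relative_tree(simulate_coalescent_tree(5, seed = 8), 50)
  tall$tip.label <- paste0("z", 1:5)
  expect_error(graft_subtree(sp, tip, tall), "exceeds the stem")
  expect_error(graft_subtree(sp, "nope", sub), "not found")
})

test_that("pairing tree distributions is uniform, sized and reproducible", {
  mk <- function(n, seed) jittered_tree_distribution(
    random_time_tree(4, seed = 1), n = n, seed = seed)
  a <- mk(10, 2); b <- mk(25, 3)
  pairs <- pair_distributions(a, b, seed = 9)
  expect_length(pairs, 10)
  pairs2 <- pair_distributions(a, b, seed = 9)
  expect_identical(lapply(pairs, function(p) p$b$edge.length),
                   lapply(pairs2, function(p) p$b$edge.length))
  # |A| = 1: the single tree is reused in every pair
  a1 <- a[1]
  p1 <- pair_distributions(a1, b, seed = 4)
  expect_length(p1, 1)
  p1b <- pair_distributions(b, a1, seed = 4)
  expect_length(p1b, 1)
  expect_error(pair_distributions(list(), b, seed = 1), "empty")
})

test_that("tree distributions read from multi-newick and NEXUS with TRANSLATE", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(rep(write_newick(tr), 3), f)
  dist <- read_tree_distribution(f, format = "multi-newick", units = "Myr")
  expect_length(dist, 3)
  expect_equal(attr(dist, "units"), "Myr")

  # hand-written two-tree NEXUS with a TRANSLATE block
  nex <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN TREES;",
    "  TRANSLATE",
    "    1 A,",
    "    2 B,",
    "    3 C;",
    "  TREE one = ((1:1,2:1):1,3:2);",
    "  TREE two = ((1:2,2:2):2,3:4);",
    "END;"), nex)
  nd <- read_tree_distribution(nex, format = "nexus", units = "Myr")
  expect_length(nd, 2)
  expect_setequal(nd[[1]]$tip.label, c("A", "B", "C"))
  expect_equal(unname(tree_height(nd[[2]])), 4)

  # heterogeneous tip sets are rejected
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:2);", "((A:1,B:1):1,D:2);"), bad)
  expect_error(read_tree_distribution(bad, format = "multi-newick"),
               "different tip set")
})

test_that("unit tags are enforced in arithmetic operations", {
  gene <- read_newick("(A:1,B:1);", units = "subs/site")
  time <- read_newick("(A:1,B:1);", units = "Myr")
  expect_error(rate_ratio(time, time), "units")
  expect_error(rate_ratio(gene, gene), "units")
  expect_silent(rate_ratio(gene, time))
  sub <- read_newick("(x:0.1,y:0.1);", units = "subs/site")
  expect_error(graft_subtree(time, "A", sub), "unit mismatch")
})
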