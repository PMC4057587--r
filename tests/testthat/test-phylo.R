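test_that("neighbor_joining validates its input matrix", {
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, dimnames = list(lab, lab))
  expect_s3_class(neighbor_joining(d), "phylo")
  expect_error(neighbor_joining(d[, 1:2]), "square")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  expect_error(neighbor_joining(unname(d)), "labels")
  d_asym <- d; d_asym[1, 2] <- 5
  expect_error(neighbor_joining(d_asym), "symmetric")
  d_diag <- d; diag(d_diag) <- 1
  expect_error(neighbor_joining(d_diag), "diagonal")
})

test_that("NJ solves the canonical additive 4-leaf case", {
  lab <- c("a", "b", "c", "d")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(lab, lab))
  tr <- neighbor_joining(d)
  expect_identical(enumerate_bipartitions(tr), "c,d")  # split ab|cd
  # internal edge length 1, pendant edges 1,2,3,4
  internal <- tr$edge[, 2] > 4
  expect_equal(unname(tr$edge.length[internal]), 1)
  tip_len <- tr$edge.length[match(1:4, tr$edge[, 2])]
  expect_equal(unname(tip_len[order(tr$tip.label)]), c(1, 2, 3, 4))
})

test_that("NJ on 3 taxa solves the three-point equations", {
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(unname(len["a"] + len["b"]), 3)
  expect_equal(unname(len["a"] + len["c"]), 4)
  expect_equal(unname(len["b"] + len["c"]), 5)
})

test_that("a zero-distance pair becomes siblings", {
  lab <- c("a", "b", "c", "d")
  d <- matrix(c(0, 0, 4, 4,
                0, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, dimnames = list(lab, lab))
  expect_identical(enumerate_bipartitions(neighbor_joining(d)), "c,d")
})

test_that("NJ recovers random additive matrices (consistency)", {
  set.seed(7201)
  for (i in 1:20) {
    case <- random_additive_case(sample(4:10, 1))
    expect_identical(
      rf_symmetric_difference(neighbor_joining(case$d), case$tree), 0L)
  }
})

test_that("bipartition enumeration yields n - 3 canonical splits", {
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_length(enumerate_bipartitions(ape::unroot(tr4)), 1)
  set.seed(7202)
  tr8 <- ape::unroot(ape::rtree(8))
  expect_length(enumerate_bipartitions(tr8), 5)
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_length(enumerate_bipartitions(star), 0)
  tr3 <- ape::read.tree(text = "(a,b,c);")
  expect_identical(enumerate_bipartitions(tr3), character(0))
})

test_that("RF examples: self, disjoint 5-leaf splits, one NNI", {
  set.seed(7203)
  tr <- ape::rtree(6)
  expect_identical(rf_symmetric_difference(tr, tr), 0L)

  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_identical(rf_symmetric_difference(t1, t2), 4L)

  n1 <- ape::read.tree(text = "(((a,b),c),(d,(e,f)));")
  n2 <- ape::read.tree(text = "(((a,c),b),(d,(e,f)));")  # one NNI apart
  expect_identical(rf_symmetric_difference(n1, n2), 2L)

  t3 <- ape::read.tree(text = "((a,b),(c,x),e);")
  expect_error(rf_symmetric_difference(t1, t3), "leaf set")
})

test_that("RF agrees with the phangorn oracle on random tree pairs", {
  set.seed(7204)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    expect_identical(rf_symmetric_difference(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("RF is a metric on random triples of 8-leaf binary trees", {
  set.seed(7205)
  for (i in 1:10) {
    labs <- paste0("t", 1:8)
    ts <- lapply(1:3, function(k) {
      tr <- ape::rtree(8); tr$tip.label <- sample(labs); tr
    })
    d12 <- rf_symmetric_difference(ts[[1]], ts[[2]])
    d13 <- rf_symmetric_difference(ts[[1]], ts[[3]])
    d23 <- rf_symmetric_difference(ts[[2]], ts[[3]])
    expect_identical(d12, rf_symmetric_difference(ts[[2]], ts[[1]]))
    expect_lte(d13, d12 + d23)            # triangle inequality
    expect_identical(rf_symmetric_difference(ts[[1]], ts[[1]]), 0L)
    if (d12 == 0L)                        # identity of indiscernibles
      expect_identical(enumerate_bipartitions(ts[[1]]),
                       enumerate_bipartitions(ts[[2]]))
  }
})

test_that("parsimony on perfect trees scores groups minus one", {
  for (sizes in list(rep(2, 15), c(13, 8, 7), c(8, 6, 5, 4))) {
    case <- perfect_grouped_tree(sizes)
    expect_identical(parsimony_score(case$tree, case$groups),
                     length(sizes) - 1L)
  }
})

test_that("parsimony handles the mixed-cherries example and missing labels", {
  tr <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  expect_identical(parsimony_score(tr, groups), 2L)
  expect_error(parsimony_score(tr, groups[-1]), "without a group")
})

test_that("parsimony matches the brute-force oracle on random trees", {
  set.seed(7206)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    groups <- stats::setNames(sample(c("X", "Y", "Z"), n, replace = TRUE),
                              tr$tip.label)
    if (length(unique(groups)) < 2) groups[1] <- setdiff(c("X", "Y"),
                                                         groups[1])[1]
    expect_identical(parsimony_score(tr, groups),
                     as.integer(brute_parsimony(tr, groups)))
  }
})

test_that("parsimony bounds and the convexity characterization hold exhaustively", {
  # All unrooted binary 6-leaf topologies, fixed 3-group labeling.  The
  # score equals g - 1 exactly when the group character is convex on the
  # tree (each group spans a node-disjoint subtree); monophyletic groups
  # are the rooted special case and always reach g - 1.
  labs <- paste0("t", 1:6)
  groups <- stats::setNames(c("A", "A", "B", "B", "C", "C"), labs)
  g <- 3L
  trees <- phangorn::allTrees(6, rooted = FALSE, tip.label = labs)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]  # [[ restores the compressed multiPhylo tip labels
    sc <- parsimony_score(tr, groups)
    expect_gte(sc, g - 1L)
    expect_lte(sc, length(labs) - 1L)
    expect_identical(sc == g - 1L, groups_convex(tr, groups))
    rooted <- ape::root(tr, outgroup = "t1", resolve.root = TRUE)
    if (all_groups_monophyletic(rooted, groups)) {
      expect_identical(sc, g - 1L)
    }
  }
})

test_that("parsimony is invariant to the rooting of an unrooted tree", {
  set.seed(7207)
  tr <- ape::unroot(ape::rtree(8))
  groups <- stats::setNames(sample(c("A", "B", "C"), 8, replace = TRUE),
                            tr$tip.label)
  base <- parsimony_score(tr, groups)
  for (node in tr$edge[, 2]) {  # reroot on every edge
    rooted <- phytools::reroot(tr, node)
    expect_identical(parsimony_score(rooted, groups), base)
  }
})

test_that("parsimony folds multifurcations gracefully", {
  tr <- ape::read.tree(text = "((A1,A2,B1),(B2,C1,C2));")
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")
  sc <- parsimony_score(tr, groups)
  expect_gte(sc, 2L)
  expect_lte(sc, 5L)
})

test_that("outgroup rooting places the root on the separating edge", {
  tr <- ape::unroot(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))

  r1 <- root_with_outgroup(tr, "a")
  expect_true(ape::is.rooted(r1))
  kids <- r1$edge[r1$edge[, 1] == length(r1$tip.label) + 1L, 2]
  expect_length(kids, 2)
  sets <- lapply(kids, function(k)
    if (k <= 4) r1$tip.label[k] else ape::extract.clade(r1, k)$tip.label)
  expect_true(any(vapply(sets, function(s) setequal(s, "a"), logical(1))))

  r2 <- root_with_outgroup(tr, c("c", "d"))
  kids2 <- r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1L, 2]
  sets2 <- lapply(kids2, function(k)
    if (k <= 4) r2$tip.label[k] else ape::extract.clade(r2, k)$tip.label)
  expect_true(any(vapply(sets2, function(s) setequal(s, c("c", "d")),
                         logical(1))))

  expect_error(root_with_outgroup(tr, letters[1:4]), "every leaf")
  expect_error(root_with_outgroup(tr, character(0)), "empty")
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")
})

test_that("rooting preserves the unrooted topology", {
  set.seed(7208)
  tr <- ape::unroot(ape::rtree(9))
  rooted <- root_with_outgroup(tr, tr$tip.label[1:2])
  expect_identical(rf_symmetric_difference(rooted, tr), 0L)
})
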