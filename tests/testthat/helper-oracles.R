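# Test oracles, all independent of the implementations they check.

# Random unrooted binary tree with branch lengths in bl_range, plus its
# additive (path-length) distance matrix.
random_additive_case <- function(n_leaves, bl_range = c(0.05, 1.0)) {
  tr <- ape::unroot(ape::rtree(n_leaves))
  tr$edge.length <- runif(nrow(tr$edge), bl_range[1], bl_range[2])
  d <- ape::cophenetic.phylo(tr)
  d <- (d + t(d)) / 2  # symmetric to the last bit
  diag(d) <- 0
  list(tree = tr, d = d)
}

# Brute-force parsimony: minimum number of edges whose endpoints carry
# different group labels, over every assignment of groups to internal
# nodes (leaves fixed by `groups`).  Exponential, fine for small trees.
brute_parsimony <- function(tree, groups) {
  tr <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  states <- sort(unique(unname(groups)))
  n <- length(tr$tip.label)
  m <- tr$Nnode
  leaf_state <- match(unname(groups[tr$tip.label]), states)
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)), m)))
  lab <- cbind(matrix(leaf_state, nrow(grid), n, byrow = TRUE), grid)
  pa <- tr$edge[, 1]
  ch <- tr$edge[, 2]
  min(rowSums(lab[, ch, drop = FALSE] != lab[, pa, drop = FALSE]))
}

# TRUE iff every group's leaves form a monophyletic clade somewhere in
# the rooted tree (checked against clade leaf sets).
all_groups_monophyletic <- function(tree, groups) {
  sets <- lapply(
    (length(tree$tip.label) + 1L):(length(tree$tip.label) + tree$Nnode),
    function(nd) ape::extract.clade(tree, nd)$tip.label)
  sets <- c(sets, as.list(tree$tip.label))  # single leaves are clades
  for (g in unique(unname(groups))) {
    members <- names(groups)[groups == g]
    ok <- any(vapply(sets, function(s) setequal(s, members), logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

# A rooted binary tree in which every group is perfectly monophyletic:
# each group is a caterpillar clade, clades joined in a caterpillar.
# Returns list(tree, groups).
perfect_grouped_tree <- function(group_sizes) {
  stopifnot(length(group_sizes) >= 2, all(group_sizes >= 1))
  caterpillar <- function(labels) {
    s <- labels[1]
    for (l in labels[-1]) s <- sprintf("(%s,%s)", s, l)
    s
  }
  leaves <- list()
  clades <- character(length(group_sizes))
  for (g in seq_along(group_sizes)) {
    labs <- sprintf("g%d_%d", g, seq_len(group_sizes[g]))
    leaves[[g]] <- labs
    clades[g] <- caterpillar(labs)
  }
  newick <- paste0(caterpillar(clades), ";")
  tree <- ape::read.tree(text = newick)
  groups <- stats::setNames(
    rep(sprintf("G%d", seq_along(group_sizes)), group_sizes),
    unlist(leaves))
  list(tree = tree, groups = groups)
}

# n random ACGTN characters as a payload string (N included so the fifth
# symbol is exercised).
random_payload <- function(n, p_n = 0.02) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# TRUE iff the group character is convex on the (unrooted) tree: the
# minimal spanning subtrees of the groups are pairwise node-disjoint.
groups_convex <- function(tree, groups) {
  n <- length(tree$tip.label)
  # adjacency over node ids
  adj <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  path_nodes <- function(from, to) {  # BFS path between two nodes
    prev <- rep(NA_integer_, length(adj))
    queue <- from; prev[from] <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      for (w in adj[[v]]) if (is.na(prev[w])) { prev[w] <- v; queue <- c(queue, w) }
    }
    path <- to
    while (path[1] != from) path <- c(prev[path[1]], path)
    path
  }
  spans <- lapply(unique(unname(groups)), function(gr) {
    tips <- match(names(groups)[groups == gr], tree$tip.label)
    nodes <- tips[1]
    for (t2 in tips[-1]) nodes <- union(nodes, path_nodes(tips[1], t2))
    nodes
  })
  for (i in seq_along(spans)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(spans[[i]], spans[[j]]))) return(FALSE)
    }
  }
  TRUE
}
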