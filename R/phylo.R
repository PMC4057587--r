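#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration on a labeled symmetric matrix with a
#' zero diagonal, returning an unrooted binary tree (`ape` "phylo"
#' object).  On an additive matrix the unique generating topology is
#' recovered and branch lengths match the generating tree.  Negative
#' branch lengths are retained by default, matching the behavior of the
#' classic PHYLIP `neighbor` program; set `clamp_negative = TRUE` to clamp
#' them at zero.
#'
#' @param d symmetric numeric matrix with labels as dimnames (for example
#'   from [pairwise_distances()]), n >= 3, zero diagonal.
#' @param clamp_negative clamp negative branch lengths at 0 (default
#'   FALSE).
#' @return an unrooted "phylo" tree on the matrix labels.
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  tr <- ape::nj(d)
  if (clamp_negative) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# leaf-label set below each edge's child, list indexed by node id
.node_leaf_sets <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  sets[seq_len(n)] <- as.list(tree$tip.label)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge, canonicalized as the
#' comma-delimited, sorted leaf set of the side that does not contain the
#' lexicographically smallest leaf label.  Trivial splits (one side a
#' single leaf, or all leaves) are excluded, so an unrooted binary tree on
#' n leaves yields exactly n - 3 bipartitions and a star tree yields none.
#'
#' @param tree a "phylo" object (rooted or unrooted).
#' @return character vector: the set of canonical bipartition keys.
#' @export
enumerate_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  ref <- min(tree$tip.label)
  sets <- .node_leaf_sets(tree)
  keys <- character(0)
  internal_children <- tree$edge[, 2][tree$edge[, 2] > n]
  for (ch in internal_children) {
    side <- sets[[ch]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Robinson-Foulds symmetric difference of two trees
#'
#' The number of internal-edge bipartitions present in exactly one of the
#' two trees (counted over both trees, as PHYLIP `treedist` does), so the
#' value is always even when both trees are binary.  Zero means identical
#' topologies.
#'
#' @param t1,t2 "phylo" trees on the same leaf set.
#' @return a non-negative integer.
#' @export
rf_symmetric_difference <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  b1 <- enumerate_bipartitions(t1)
  b2 <- enumerate_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Leaf-label parsimony score of a clustering tree
#'
#' Measures how far a tree is from making every group of a true
#' classification monophyletic.  The score starts at 0 and the leaves are
#' labeled with their groups; moving from the leaves toward the root, each
#' internal node receives the intersection of its children's label sets
#' if that intersection is non-empty, otherwise their union with a
#' penalty of 1.  A perfect clustering tree scores g - 1 where g is the
#' number of groups; higher scores mean a worse match.  The score does not
#' depend on where an unrooted tree is rooted, so unrooted input is
#' accepted as-is.  Multifurcating nodes fold their children left to
#' right with the same intersection/union rule.
#'
#' @param tree a "phylo" tree whose tips all appear in `groups`.
#' @param groups named character vector mapping leaf label to group
#'   identifier (see [read_label_map()]).
#' @return non-negative integer penalty count.
#' @export
parsimony_score <- function(tree, groups) {
  n <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(groups))
  if (length(missing_tips))
    stop("leaves without a group label: ",
         paste(missing_tips, collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  lab <- vector("list", n + tree$Nnode)
  lab[seq_len(n)] <- as.list(unname(groups[tree$tip.label]))
  penalty <- 0L
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    s <- lab[[ch]]
    if (is.null(lab[[p]])) {
      lab[[p]] <- s
    } else {
      inter <- intersect(lab[[p]], s)
      if (length(inter)) {
        lab[[p]] <- inter
      } else {
        lab[[p]] <- union(lab[[p]], s)
        penalty <- penalty + 1L
      }
    }
  }
  penalty
}

#' Root an unrooted tree with an outgroup
#'
#' Places the root at the midpoint of the edge separating the outgroup
#' leaves from the rest.  If no single edge separates the outgroup exactly
#' (the outgroup is not a clade in the unrooted tree), the edge whose
#' split disagrees with the outgroup on the fewest leaves is used.
#'
#' @param tree an unrooted "phylo" tree.
#' @param outgroup character vector of leaf labels; must be a non-empty
#'   proper subset of the leaves.
#' @return a rooted "phylo" tree whose root has two children.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (length(outgroup) == 0) stop("outgroup is empty")
  unknown <- setdiff(outgroup, tips)
  if (length(unknown))
    stop("outgroup labels not in tree: ", paste(unknown, collapse = ", "))
  if (setequal(outgroup, tips))
    stop("outgroup cannot contain every leaf")
  sets <- .node_leaf_sets(tree)
  # pick the edge whose child-side split best matches the outgroup
  best_node <- NA_integer_; best_miss <- Inf; best_key <- ""
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    side <- sets[[ch]]
    miss <- min(length(setdiff(side, outgroup)) +
                  length(setdiff(outgroup, side)),
                length(setdiff(setdiff(tips, side), outgroup)) +
                  length(intersect(outgroup, side)))
    key <- paste(sort(side), collapse = ",")
    if (miss < best_miss || (miss == best_miss && key < best_key)) {
      best_miss <- miss; best_node <- ch; best_key <- key
    }
  }
  elen <- tree$edge.length[which(tree$edge[, 2] == best_node)]
  pos <- if (is.null(elen) || length(elen) == 0 || is.na(elen)) 0 else elen / 2
  rooted <- phytools::reroot(tree, best_node, position = pos)
  rooted
}
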