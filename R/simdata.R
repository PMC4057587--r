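BASES <- c("A", "C", "G", "T")

# substitute bases at the given per-base rate, uniformly among the other
# three; N positions are left untouched
.mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate & chars != "N")
  if (length(hit)) {
    old <- match(chars[hit], BASES) - 1L
    offset <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((old + offset) %% 4L) + 1L]
  }
  chars
}

.with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

#' Random i.i.d. genome
#'
#' Bases are drawn independently with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(T) = (1 - `gc_fraction`)/2.
#'
#' @param length genome length in bases (>= 1).
#' @param gc_fraction expected G+C fraction in \[0, 1\] (default 0.5).
#' @param seed optional integer seed for reproducibility.
#' @return an `nt_payload`.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(length >= 1)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  chars <- .with_optional_seed(seed,
    sample(BASES, length, replace = TRUE, prob = p))
  structure(paste(chars, collapse = ""), class = "nt_payload",
            n_replaced = 0L)
}

#' Random guide tree for benchmark clades
#'
#' A random binary topology with branch lengths drawn uniformly from
#' `bl_range` (expected substitutions per site), for use with
#' [evolve_along_tree()].
#'
#' @param n_leaves number of leaves (>= 3).
#' @param bl_range length-2 numeric, min and max branch length.
#' @param seed optional integer seed.
#' @return a rooted "phylo" tree with tip labels t1..tn.
#' @export
random_guide_tree <- function(n_leaves, bl_range = c(0.02, 0.3),
                              seed = NULL) {
  stopifnot(n_leaves >= 3, length(bl_range) == 2, all(bl_range >= 0))
  .with_optional_seed(seed, {
    tr <- ape::rtree(n_leaves)
    tr$edge.length <- runif(nrow(tr$edge), bl_range[1], bl_range[2])
    tr
  })
}

#' Evolve a root genome along a tree (Jukes-Cantor)
#'
#' Sites evolve independently down each branch: for branch length d
#' (expected substitutions per site) the per-site substitution probability
#' is p = (3/4)(1 - exp(-4d/3)); a substituted site takes one of the
#' three other bases uniformly.  Leaves inherit the root's length exactly
#' (no indels); N sites are carried through unchanged.
#'
#' @param root an `nt_payload` (or string), the ancestral genome.
#' @param guide_tree rooted "phylo" tree with non-negative branch lengths
#'   in expected substitutions/site.
#' @param seed optional integer seed.
#' @return named list of `nt_payload`s, one per leaf label.
#' @export
evolve_along_tree <- function(root, guide_tree, seed = NULL) {
  root <- as_payload(root)
  if (nchar(root) == 0) stop("root genome is empty")
  if (!ape::is.rooted(guide_tree)) stop("guide tree must be rooted")
  if (is.null(guide_tree$edge.length) || any(guide_tree$edge.length < 0))
    stop("guide tree must have non-negative branch lengths")
  n <- length(guide_tree$tip.label)
  .with_optional_seed(seed, {
    seqs <- vector("list", n + guide_tree$Nnode)
    root_node <- n + 1L
    seqs[[root_node]] <- strsplit(unclass(root), "")[[1]]
    # preorder: parents before children
    ord <- ape::reorder.phylo(guide_tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      d <- ord$edge.length[e]
      prob <- 0.75 * (1 - exp(-4 * d / 3))
      seqs[[ch]] <- .mutate_chars(seqs[[p]], prob)
    }
    out <- lapply(seq_len(n), function(i)
      structure(paste(seqs[[i]], collapse = ""), class = "nt_payload",
                n_replaced = 0L))
    names(out) <- guide_tree$tip.label
    out
  })
}

#' Simulate NGS short reads from a genome
#'
#' Reads of fixed length are drawn uniformly (with replacement) from the
#' forward strand; the number of reads is `round(depth * L /
#' read_length)` so total simulated bases match the requested coverage to
#' within one read.  Error models are uniform-substitution stand-ins for
#' sequencing platforms: "exact" introduces no errors (every read is a
#' verbatim substring), "illumina_like" substitutes at 0.01/base,
#' "sanger_like" and "ls454_like" at 0.005/base; `substitution_rate`
#' overrides the model default.
#'
#' @param genome an `nt_payload` (or string), length >= `read_length`.
#' @param depth coverage depth (x), positive.
#' @param read_length read length in bases (default 100).
#' @param error_model one of "exact", "illumina_like", "sanger_like",
#'   "ls454_like".
#' @param substitution_rate optional per-base substitution rate in
#'   \[0, 0.75\]; must be 0 (or omitted) for the exact model.
#' @param random_strand if TRUE each read is reverse-complemented with
#'   probability 1/2 (default FALSE, forward strand only).
#' @param seed optional integer seed.
#' @return character vector of reads.
#' @export
simulate_reads <- function(genome, depth, read_length = 100L,
                           error_model = c("exact", "illumina_like",
                                           "sanger_like", "ls454_like"),
                           substitution_rate = NULL,
                           random_strand = FALSE, seed = NULL) {
  error_model <- match.arg(error_model)
  genome <- as_payload(genome)
  L <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length < 1 || read_length > L)
    stop("read_length must be between 1 and the genome length")
  stopifnot(depth > 0)
  if (is.null(substitution_rate)) {
    substitution_rate <- switch(error_model, exact = 0,
                                illumina_like = 0.01,
                                sanger_like = 0.005, ls454_like = 0.005)
  }
  if (substitution_rate < 0 || substitution_rate > 0.75)
    stop("substitution_rate must be in [0, 0.75]")
  if (error_model == "exact" && substitution_rate != 0)
    stop("the exact error model requires substitution_rate = 0")
  n_reads <- max(1L, as.integer(round(depth * L / read_length)))
  .with_optional_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    reads <- substring(unclass(genome), starts, starts + read_length - 1L)
    if (substitution_rate > 0) {
      chars <- strsplit(paste(reads, collapse = ""), "")[[1]]
      chars <- .mutate_chars(chars, substitution_rate)
      all <- paste(chars, collapse = "")
      ends <- seq_len(n_reads) * read_length
      reads <- substring(all, ends - read_length + 1L, ends)
    }
    if (random_strand) {
      flip <- runif(n_reads) < 0.5
      if (any(flip)) {
        rc <- chartr("ACGT", "TGCA",
                     vapply(strsplit(reads[flip], ""), function(ch)
                       paste(rev(ch), collapse = ""), character(1)))
        reads[flip] <- rc
      }
    }
    reads
  })
}
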