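#' Read a FASTA file into a sample set
#'
#' Record headers become sample labels (duplicates are an error) and the
#' sequences are sanitized to the \{A,C,G,T,N\} alphabet.
#'
#' @param path FASTA file path.
#' @param source_kind passed to [sample_set()].
#' @return a [sample_set()].
#' @export
read_fasta <- function(path, source_kind = "long_sequence") {
  seqs <- Biostrings::readDNAStringSet(path)
  labels <- names(seqs)
  if (anyDuplicated(labels))
    stop("duplicate FASTA headers in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  payloads <- lapply(as.character(seqs), sanitize)
  names(payloads) <- labels
  sample_set(payloads, source_kind = source_kind)
}

#' Read a FASTQ file as a vector of reads
#'
#' Quality lines are parsed and discarded; only the nucleotide content
#' matters for compression distances.
#'
#' @param path FASTQ file path.
#' @return character vector of sanitized reads.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  vapply(as.character(seqs), function(s) unclass(sanitize(s)), character(1),
         USE.NAMES = FALSE)
}

#' Write sequences to FASTA or reads to FASTA/FASTQ
#'
#' `write_fasta()` writes a named list/vector of sequences (or a
#' [sample_set()]).  `write_reads()` writes a read vector, as FASTA or as
#' FASTQ with a constant quality of "I".
#'
#' @param x sequences: a `sample_set`, or a named list/character vector.
#' @param path output file path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "sample_set")) {
    seqs <- vapply(x$payloads, unclass, character(1))
    names(seqs) <- x$labels
  } else {
    seqs <- vapply(x, function(p) unclass(as_payload(p)), character(1))
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param reads character vector of reads.
#' @param format "fasta" or "fastq".
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  names(reads) <- paste0("read", seq_along(reads))
  ss <- Biostrings::DNAStringSet(reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path)
  } else {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    qss <- Biostrings::QualityScaledDNAStringSet(
      ss, Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(qss, path)
  }
  invisible(path)
}

#' Write/read PHYLIP distance matrices
#'
#' The "square" dialect is what the classic PHYLIP `neighbor` program
#' expects: a taxon-count line, then one row per taxon with the label
#' padded to 10 characters followed by the values.  Labels longer than 10
#' characters are truncated; a collision after truncation is an error.
#' The "relaxed" dialect keeps full labels, tab-separated, and round-trips
#' losslessly.
#'
#' @param d labeled symmetric matrix.
#' @param path file path.
#' @param dialect "square" or "relaxed".
#' @return `read_phylip_matrix()` returns the labeled matrix.
#' @export
write_phylip_matrix <- function(d, path, dialect = c("square", "relaxed")) {
  dialect <- match.arg(dialect)
  d <- unclass(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (dialect == "square") {
    short <- substr(labels, 1, 10)
    if (anyDuplicated(short))
      stop("labels collide after truncation to 10 characters: ",
           paste(unique(short[duplicated(short)]), collapse = ", "))
    rows <- vapply(seq_len(n), function(i)
      paste0(formatC(short[i], width = -10),
             paste(sprintf("%.6f", d[i, ]), collapse = " ")),
      character(1))
  } else {
    rows <- vapply(seq_len(n), function(i)
      paste(c(labels[i], sprintf("%.17g", d[i, ])), collapse = "\t"),
      character(1))
  }
  writeLines(c(sprintf("%5d", n), rows), path)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path, dialect = c("square", "relaxed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1)
    stop("malformed PHYLIP matrix: ", path)
  labels <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1]
    if (dialect == "square") {
      labels[i] <- trimws(substr(row, 1, 10))
      vals <- scan(text = substring(row, 11), quiet = TRUE)
    } else {
      parts <- strsplit(row, "\t", fixed = TRUE)[[1]]
      labels[i] <- parts[1]
      vals <- as.numeric(parts[-1])
    }
    if (length(vals) != n) stop("row ", i, " has ", length(vals),
                                " values, expected ", n)
    d[i, ] <- vals
  }
  dimnames(d) <- list(labels, labels)
  d
}

#' Read/write leaf-to-group label maps
#'
#' A label map is a two-column TSV (leaf label, group) defining the true
#' classification used by [parsimony_score()].
#'
#' @param path TSV file path.
#' @param groups named character vector, names are leaf labels.
#' @return `read_label_map()` returns a named character vector.
#' @export
read_label_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("leaf", "group"),
                           colClasses = "character")
  if (anyDuplicated(tab$leaf))
    stop("duplicate leaf labels in label map: ",
         paste(unique(tab$leaf[duplicated(tab$leaf)]), collapse = ", "))
  stats::setNames(tab$group, tab$leaf)
}

#' @rdname read_label_map
#' @export
write_label_map <- function(groups, path) {
  utils::write.table(data.frame(leaf = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.quote_label <- function(lab) {
  if (any(grepl("'", lab, fixed = TRUE)))
    stop("labels containing a single quote cannot be written to Newick")
  ifelse(grepl("[][ ():,;]", lab), paste0("'", lab, "'"), lab)
}

#' Read and write Newick trees
#'
#' `read_newick()` wraps `ape::read.tree`.  `write_newick()` serializes
#' deterministically: at every internal node the children are ordered by
#' their smallest descendant leaf label, so topologically identical trees
#' always produce identical strings.  Labels containing Newick
#' metacharacters are single-quoted; labels containing a single quote are
#' rejected (no portable Newick encoding exists for them).
#'
#' @param tree a "phylo" object.
#' @param path optional output path; if NULL the Newick string is
#'   returned.
#' @param digits significant digits for branch lengths.
#' @return `write_newick()`: the Newick string (invisibly when writing to
#'   a file); `read_newick()`: a "phylo" object.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  n <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  sets <- .node_leaf_sets(tree)
  smallest <- vapply(sets, function(s)
    if (is.null(s)) "" else min(s), character(1))
  rec <- function(node) {
    if (node <= n) return(.quote_label(tree$tip.label[node]))
    ke <- kids[[as.character(node)]]
    ch <- tree$edge[ke, 2]
    ord <- order(smallest[ch])
    parts <- vapply(ord, function(k) {
      s <- rec(ch[k])
      if (has_len)
        s <- paste0(s, ":", format(tree$edge.length[ke[k]], digits = digits,
                                   scientific = FALSE, trim = TRUE))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  str <- paste0(rec(n + 1L), ";")
  if (!is.null(path)) {
    writeLines(str, path)
    return(invisible(str))
  }
  str
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  # ape keeps single quotes verbatim; strip them to invert .quote_label
  unquote <- function(x) sub("^'(.*)'$", "\\1", x)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
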