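#' Compression-based distance measures
#'
#' Scalar forms of the three distances, taking compressed sizes in bytes:
#' \describe{
#'   \item{`dist_cdm`}{the compression-based dissimilarity measure
#'     `C(xy) / (C(x) + C(y))`, ranging from 1/2 (identical inputs) to 1
#'     (inputs sharing no information);}
#'   \item{`dist_cond`}{the conditional-compression distance
#'     `(C(x|y) + C(y|x)) / C(xy)`, ranging from 0 to 1;}
#'   \item{`dist_ncd`}{the normalized compression distance
#'     `max(C(x|y), C(y|x)) / max(C(x), C(y))`, a proper metric under
#'     idealized compression, ranging from 0 to 1.}
#' }
#'
#' @param c_x,c_y compressed sizes C(x), C(y).
#' @param c_xy compressed size of the concatenation, C(xy).
#' @param c_x_given_y,c_y_given_x conditional sizes C(x|y), C(y|x).
#' @return a single non-negative numeric distance.
#' @examples
#' dist_cdm(100, 150, 250)        # no shared information -> 1
#' dist_cond(200, 100, 100)       # independence limit    -> 1
#' dist_ncd(100, 100, 0, 0)       # identity limit        -> 0
#' @export
dist_cdm <- function(c_x, c_y, c_xy) {
  if (c_x + c_y == 0) stop("C(x) + C(y) must be positive")
  c_xy / (c_x + c_y)
}

#' @rdname dist_cdm
#' @export
dist_cond <- function(c_xy, c_x_given_y, c_y_given_x) {
  if (c_xy == 0) stop("C(xy) must be positive")
  (c_x_given_y + c_y_given_x) / c_xy
}

#' @rdname dist_cdm
#' @export
dist_ncd <- function(c_x, c_y, c_x_given_y, c_y_given_x) {
  if (max(c_x, c_y) == 0) stop("max(C(x), C(y)) must be positive")
  max(c_x_given_y, c_y_given_x) / max(c_x, c_y)
}

#' Bundle labeled payloads into a sample set
#'
#' One element per sample: either a long genomic sequence or the
#' concatenation of an NGS sample's short reads (see
#' [sample_from_reads()]).
#'
#' @param payloads named list (or character vector) of payloads; names are
#'   the sample labels and must be unique and non-empty.
#' @param source_kind "long_sequence" or "read_sample".
#' @return an object of class `sample_set`.
#' @export
sample_set <- function(payloads, source_kind = c("long_sequence",
                                                 "read_sample")) {
  source_kind <- match.arg(source_kind)
  labels <- names(payloads)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every payload must carry a non-empty label (name)")
  if (anyDuplicated(labels))
    stop("duplicate sample labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  payloads <- lapply(payloads, as_payload)
  structure(list(labels = labels, payloads = payloads,
                 source_kind = source_kind),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d %s samples>\n", length(x$labels),
              sub("_", " ", x$source_kind)))
  for (i in seq_along(x$labels))
    cat(sprintf("  %s (%d nt)\n", x$labels[i], nchar(x$payloads[[i]])))
  invisible(x)
}

#' Concatenate an NGS sample's short reads into one payload
#'
#' A read sample is compared by first concatenating all of its reads into
#' a single sequence (no separator symbol, so the payload length is the
#' sum of the read lengths) and compressing that.  The distances are
#' empirically robust to the concatenation order; `order_seed` applies a
#' seeded uniform shuffle before concatenation so that robustness can be
#' measured.
#'
#' @param reads character vector of reads (sanitized on the fly).
#' @param order_seed optional integer; if given, reads are shuffled with
#'   this seed before concatenation, otherwise file order is kept.
#' @return an `nt_payload`.
#' @export
sample_from_reads <- function(reads, order_seed = NULL) {
  if (length(reads) == 0) stop("read list is empty")
  reads <- vapply(reads, function(r) unclass(as_payload(r)), character(1))
  if (!is.null(order_seed)) {
    reads <- withr::with_seed(as.integer(order_seed), sample(reads))
  }
  structure(paste(reads, collapse = ""), class = "nt_payload",
            n_replaced = 0L)
}

#' Pairwise compression-distance matrix over a sample set
#'
#' Computes the chosen measure for every pair of samples.  Unconditional
#' sizes C(x) are computed once per sample and cached; the joint payload
#' of a pair is always concatenated in a canonical order (sorted by
#' label), which makes the matrix exactly symmetric without doubling the
#' compression work.  The diagonal is 0 by convention (the PHYLIP tools
#' downstream expect zero self-distance) even though the raw CDM
#' self-value is about 1/2; the raw value remains available through the
#' scalar operations.
#'
#' @param samples a [sample_set()] with at least two samples, all payloads
#'   non-empty.
#' @param measure "cdm", "cond" or "ncd".
#' @param backend a [compressor_backend()]; defaults to the built-in
#'   coder at its default context order.  A warning is emitted when "cond" or "ncd" is requested from a
#'   backend whose conditional sizes are only approximate.
#' @return a symmetric numeric matrix with the sample labels as dimnames,
#'   of class `c("compression_dist", "matrix")`.
#' @export
pairwise_distances <- function(samples,
                               measure = c("cdm", "cond", "ncd"),
                               backend = compressor_backend("builtin")) {
  measure <- match.arg(measure)
  stopifnot(inherits(samples, "sample_set"))
  n <- length(samples$labels)
  if (n < 2) stop("need at least two samples")
  if (any(vapply(samples$payloads, nchar, 1L) == 0L))
    stop("all payloads must be non-empty")
  if (measure != "cdm" && !backend$supports_conditional)
    warning("backend '", backend$name, "' approximates C(x|y) as ",
            "max(C(yx) - C(y), 0)")

  labels <- samples$labels
  pay <- samples$payloads
  c_x <- vapply(pay, function(p) as.numeric(compress_size(backend, p)),
                numeric(1))

  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # canonical order: the label-sorted first sample leads the pair
      a <- i; b <- j
      if (labels[j] < labels[i]) { a <- j; b <- i }
      val <- switch(measure,
        cdm = {
          c_ab <- compress_size(
            backend, paste0(unclass(pay[[a]]), unclass(pay[[b]])))
          dist_cdm(c_x[a], c_x[b], c_ab)
        },
        cond = {
          c_ab <- compress_size(
            backend, paste0(unclass(pay[[a]]), unclass(pay[[b]])))
          dist_cond(c_ab,
                    conditional_size(backend, pay[[a]], pay[[b]]),
                    conditional_size(backend, pay[[b]], pay[[a]]))
        },
        ncd = dist_ncd(c_x[a], c_x[b],
                       conditional_size(backend, pay[[a]], pay[[b]]),
                       conditional_size(backend, pay[[b]], pay[[a]]))
      )
      d[i, j] <- d[j, i] <- val
    }
  }
  class(d) <- c("compression_dist", "matrix")
  d
}

#' Row-concatenation Pearson correlation of two distance matrices
#'
#' Each matrix is flattened into a single vector by concatenating its rows
#' side by side and the Pearson correlation of the two vectors is
#' returned.  The default follows that procedure literally: the zero
#' diagonal and both triangles are included.  Set
#' `include_diagonal = FALSE` to correlate only the upper off-diagonal
#' entries.
#'
#' @param d1,d2 square numeric matrices with identical labels in identical
#'   order.
#' @param include_diagonal include the diagonal (and both triangles) in the
#'   flattened vectors (default TRUE).
#' @return Pearson correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(d1, d2, include_diagonal = TRUE) {
  d1 <- unclass(d1); d2 <- unclass(d2)
  if (!identical(dim(d1), dim(d2)) ||
      !identical(rownames(d1), rownames(d2)))
    stop("matrices must have identical labels in identical order")
  if (include_diagonal) {
    v1 <- as.vector(t(d1)); v2 <- as.vector(t(d2))
  } else {
    keep <- upper.tri(d1)
    v1 <- d1[keep]; v2 <- d2[keep]
  }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("cannot correlate a constant distance vector")
  stats::cor(v1, v2)
}
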