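#' Sanitize raw nucleotide text into a payload
#'
#' Uppercases, strips whitespace, maps U to T and every other IUPAC
#' ambiguity code (R, Y, S, W, K, M, B, D, H, V) to N.  The five-letter
#' alphabet \{A,C,G,T,N\} is what every compression backend consumes; N is
#' kept as a first-class symbol so that payload lengths (and hence read
#' counts and coverage depths) are preserved.
#'
#' @param raw_text a character scalar of sequence text (headers already
#'   removed).
#' @return a character scalar of class `nt_payload` over \{A,C,G,T,N\},
#'   with attribute `n_replaced` giving the number of ambiguity codes
#'   mapped to N.
#' @examples
#' sanitize("acgt")
#' sanitize("ACRGT")   # R -> N, one replacement
#' @export
sanitize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  s <- toupper(gsub("[ \t\r\n\v\f]", "", raw_text))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", s)
  if (nzchar(bad)) {
    stop("non-IUPAC nucleotide characters in input: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  }
  n_amb <- nchar(s) - nchar(gsub("[RYSWKMBDHV]", "", s))
  s <- gsub("[RYSWKMBDHV]", "N", s)
  structure(s, class = "nt_payload", n_replaced = n_amb)
}

#' @export
print.nt_payload <- function(x, ...) {
  n <- nchar(x)
  head <- substr(x, 1L, 60L)
  cat(sprintf("<nt_payload: %d nt%s>\n", n, if (n > 60) "..." else ""))
  cat(head, if (n > 60) "...", "\n", sep = "")
  invisible(x)
}

as_payload <- function(x) {
  if (inherits(x, "nt_payload")) x else sanitize(as.character(x))
}

#' Compression backends
#'
#' The distance measures only need compressed sizes, so any compressor can
#' stand behind them.  The built-in backend is an adaptive
#' mixture-of-context-models coder (orders 0 to `context_order` plus a
#' repeat-match expert) with arithmetic coding over \{A,C,G,T,N\} (see
#' [encode_payload()]); it is the only backend with true conditional
#' compression, obtained by priming the context model with a full pass
#' over the conditioning payload.  The general-purpose backends ("gzip",
#' "bzip2", "xz") measure sizes with [memCompress()] and approximate
#' conditional sizes as `max(C(yx) - C(y), 0)`.
#'
#' @param name one of "builtin", "gzip", "bzip2", "xz".
#' @param context_order deepest context length (previous symbols) of the
#'   built-in model mixture; ignored by the other backends.  Default 8.
#' @return an object of class `compressor_backend`.
#' @examples
#' b <- compressor_backend("builtin")
#' compress_size(b, sanitize("ACGTACGTACGT"))
#' @export
compressor_backend <- function(name = c("builtin", "gzip", "bzip2", "xz"),
                               context_order = 8L) {
  name <- match.arg(name)
  context_order <- as.integer(context_order)
  if (name == "builtin" && (context_order < 1L || context_order > 8L))
    stop("context_order must be between 1 and 8")
  structure(
    list(name = name,
         supports_conditional = name == "builtin",
         context_order = context_order,
         header_bytes = if (name == "builtin") 8L else 0L),
    class = "compressor_backend"
  )
}

#' @export
print.compressor_backend <- function(x, ...) {
  cat(sprintf("<compressor_backend '%s'%s, conditional: %s>\n", x$name,
              if (x$name == "builtin")
                sprintf(" (order %d)", x$context_order) else "",
              if (x$supports_conditional) "native" else "approximate"))
  invisible(x)
}

#' Compressed size C(x) in bytes
#'
#' For the built-in coder the size is `ceiling(code bits / 8) +
#' header_bytes` with an 8-byte header (the symbol count of the bitstream
#' format), identical to `length(encode_payload(x))`.  For the
#' general-purpose backends it is the length of the [memCompress()]
#' output.  Deterministic for a fixed backend configuration.
#'
#' @param backend a [compressor_backend()].
#' @param x a sanitized payload (or character string, sanitized on the fly).
#' @return integer number of bytes.
#' @export
compress_size <- function(backend, x) {
  stopifnot(inherits(backend, "compressor_backend"))
  x <- as_payload(x)
  if (backend$name == "builtin") {
    bits <- .cg_size_bits(unclass(x), backend$context_order)
    as.integer(ceiling(bits / 8) + backend$header_bytes)
  } else {
    length(memCompress(charToRaw(unclass(x)), type = backend$name))
  }
}

#' Conditional compressed size C(x|y) in bytes
#'
#' With the built-in coder the context model is first primed by a full
#' pass over `y` (counts updated, nothing emitted) and `x` is then coded;
#' the reported size is `min(primed bits, unprimed bits) + 1` flag bit,
#' rounded up to bytes, plus the header.  Taking the better of the primed
#' and unprimed model (at the cost of one flag bit) guarantees
#' `C(x|y) <= C(x) + header_bytes` even when `y` is unrelated to `x`.
#' Backends without conditional support fall back to the standard
#' approximation `max(C(yx) - C(y), 0)`; the result then carries the
#' attribute `approximate = TRUE`.
#'
#' @inheritParams compress_size
#' @param y the conditioning payload.
#' @return integer number of bytes; near 0 when `x` is essentially a copy
#'   of `y`, near `compress_size(backend, x)` when they are unrelated.
#' @export
conditional_size <- function(backend, x, y) {
  stopifnot(inherits(backend, "compressor_backend"))
  x <- as_payload(x)
  y <- as_payload(y)
  if (backend$supports_conditional) {
    primed <- .cg_cond_size_bits(unclass(x), unclass(y),
                                 backend$context_order)
    plain <- .cg_size_bits(unclass(x), backend$context_order)
    as.integer(ceiling((min(primed, plain) + 1) / 8) + backend$header_bytes)
  } else {
    c_y <- compress_size(backend, y)
    c_yx <- compress_size(backend, sanitize(paste0(unclass(y), unclass(x))))
    structure(max(c_yx - c_y, 0L), approximate = TRUE)
  }
}

#' Lossless encode/decode with the built-in coder
#'
#' `encode_payload()` produces the bitstream of the built-in coder: an
#' 8-byte big-endian symbol count followed by the arithmetic-coded
#' payload.  `decode_payload()` inverts it exactly;
#' `decode_payload(encode_payload(p)) == p` for every payload including
#' the empty one.  Decoding raises an error on streams that are truncated
#' or otherwise structurally corrupt.
#'
#' @param x a payload (class `nt_payload` or character).
#' @param bitstream a raw vector produced by `encode_payload()`.
#' @param context_order context length of the model; must match between
#'   encode and decode.
#' @return `encode_payload()`: a raw vector. `decode_payload()`: an
#'   `nt_payload`.
#' @examples
#' p <- sanitize("ACGTNACGT")
#' identical(unclass(decode_payload(encode_payload(p))), unclass(p))
#' @export
encode_payload <- function(x, context_order = 8L) {
  x <- as_payload(x)
  .cg_encode(unclass(x), as.integer(context_order))
}

#' @rdname encode_payload
#' @export
decode_payload <- function(bitstream, context_order = 8L) {
  stopifnot(is.raw(bitstream))
  structure(.cg_decode(bitstream, as.integer(context_order)),
            class = "nt_payload", n_replaced = 0L)
}
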