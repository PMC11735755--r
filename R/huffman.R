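# Static entropy coder for non-negative integer streams: canonical Huffman
# with an explicit code-length table serialized ahead of the bit payload.
# Degenerate inputs (empty stream, single distinct value) are handled by
# count-only headers, so every stream has a well-defined encoding.

huffman_code_lengths <- function(freq) {
  k <- length(freq)
  if (k == 1) return(0L)
  w <- as.numeric(freq)
  groups <- as.list(seq_len(k))
  depth <- integer(k)
  while (length(w) > 1) {
    o <- order(w)[1:2]
    leaves <- c(groups[[o[1]]], groups[[o[2]]])
    depth[leaves] <- depth[leaves] + 1L
    keep <- setdiff(seq_along(w), o)
    w <- c(w[keep], w[o[1]] + w[o[2]])
    groups <- c(groups[keep], list(leaves))
  }
  if (max(depth) > 48) grass_error("entropy code too deep", "grass_internal")
  depth
}

# canonical code numbers for symbols with given lengths (MSB-first)
canonical_codes <- function(values, lens) {
  o <- order(lens, values)
  codes <- numeric(length(values))
  code <- 0
  prev <- lens[o[1]]
  for (idx in seq_along(o)) {
    i <- o[idx]
    if (idx > 1) code <- (code + 1) * 2^(lens[i] - prev)
    prev <- lens[i]
    codes[i] <- code
  }
  codes
}

code_to_bits <- function(code, len) {
  if (len == 0) return(integer(0))
  (code %/% 2^((len - 1):0)) %% 2
}

#' Encode non-negative integers with a static canonical Huffman code
#'
#' Builds a canonical Huffman code over the multiset of `values` and
#' serializes a self-delimiting payload: total count, the sorted distinct
#' values (delta-coded), their code lengths, then the bit stream. Empty and
#' single-symbol inputs are represented by count-only headers.
#'
#' @param values numeric vector of non-negative integers.
#' @return a raw vector; decode with [entropy_decode_values()].
#' @seealso [entropy_decode_values()]
#' @export
entropy_encode_values <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) return(varint_encode(0))
  if (any(values < 0) || any(values != floor(values))) {
    grass_error("entropy coder accepts non-negative integers only", "grass_internal")
  }
  alphabet <- sort(unique(values))
  k <- length(alphabet)
  freq <- tabulate(match(values, alphabet), nbins = k)
  lens <- huffman_code_lengths(freq)
  header <- c(
    varint_encode(n),
    varint_encode(k),
    varint_encode(c(alphabet[1], diff(alphabet))),
    varint_encode(lens)
  )
  if (k == 1) return(header)
  codes <- canonical_codes(alphabet, lens)
  bitlist <- lapply(seq_len(k), function(i) code_to_bits(codes[i], lens[i]))
  bits <- unlist(bitlist[match(values, alphabet)], use.names = FALSE)
  c(header, varint_encode(length(bits)), pack_bitvec(bits))
}

#' Decode a canonical-Huffman payload produced by [entropy_encode_values()]
#'
#' @param reader either a raw vector or an internal byte cursor. When given a
#'   raw vector the payload must span it exactly.
#' @return numeric vector of the decoded values.
#' @export
entropy_decode_values <- function(reader) {
  standalone <- is.raw(reader)
  if (standalone) reader <- new_reader(reader)
  n <- read_varint(reader)
  if (n == 0) {
    if (standalone && reader_remaining(reader) > 0) stop_corrupt("trailing bytes after entropy payload")
    return(numeric(0))
  }
  k <- read_varint(reader)
  alphabet <- cumsum(read_varints(reader, k))
  lens <- read_varints(reader, k)
  if (k == 1) {
    out <- rep(alphabet, n)
  } else {
    nbits <- read_varint(reader)
    payload <- read_bytes(reader, ceiling(nbits / 8))
    bits <- unpack_bitvec(payload)
    if (length(bits) < nbits) stop_corrupt("truncated entropy payload")
    # canonical decoding tables per code length
    o <- order(lens, alphabet)
    syms <- alphabet[o]
    slen <- lens[o]
    maxlen <- max(slen)
    count <- tabulate(slen, nbins = maxlen)
    first_code <- numeric(maxlen)
    first_index <- integer(maxlen)
    code <- 0; idx <- 1L
    for (L in seq_len(maxlen)) {
      first_code[L] <- code
      first_index[L] <- idx
      code <- (code + count[L]) * 2
      idx <- idx + count[L]
    }
    out <- numeric(n)
    got <- 0L; acc <- 0; L <- 0L; bi <- 1L
    while (got < n) {
      if (bi > nbits) stop_corrupt("truncated entropy payload")
      acc <- acc * 2 + bits[bi]
      bi <- bi + 1L
      L <- L + 1L
      if (L <= maxlen && count[L] > 0 && acc - first_code[L] < count[L]) {
        got <- got + 1L
        out[got] <- syms[first_index[L] + acc - first_code[L]]
        acc <- 0; L <- 0L
      } else if (L >= maxlen) {
        stop_corrupt("invalid entropy code")
      }
    }
  }
  if (standalone && reader_remaining(reader) > 0) stop_corrupt("trailing bytes after entropy payload")
  out
}
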