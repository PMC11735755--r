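# Encoding-phase transforms over the core nucleotide stream. The five-symbol
# stream (A, C, G, T-or-U, N) is reduced to three symbols by a grammar rule
# that rewrites the three rarest symbols as two-character codewords flagged
# by 'Z', relabelled as digits 0/1/2, and halved by pairing adjacent digits
# into one of nine symbols. Every transform has an exact inverse.

CORE_SYMBOLS <- c("A", "C", "G", "T", "N")
PAIR_SYMBOLS <- c("P", "Q", "S", "R", "V", "W", "U", "X", "Y") # index = 3*d1 + d2 + 1

#' Tally core-alphabet symbol frequencies
#'
#' Counts A, C, G, T and N in the core stream. For RNA streams U is counted
#' in the T slot (the codec maps U to T before the encoding phase).
#'
#' @param core a single string over the core alphabet `A,C,G,T,N`.
#' @return named integer vector with elements A, C, G, T, N summing to
#'   `nchar(core)`.
#' @export
count_frequencies <- function(core) {
  stopifnot(is.character(core), length(core) == 1)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  if (nchar(core) == 0) return(counts)
  ints <- utf8ToInt(core)
  idx <- match(ints, utf8ToInt(paste(CORE_SYMBOLS, collapse = "")))
  if (anyNA(idx)) {
    grass_error("core stream contains a symbol outside A,C,G,T,N", "grass_internal")
  }
  counts[seq_along(CORE_SYMBOLS)] <- tabulate(idx, nbins = 5L)
  counts
}

#' Rank the five core symbols by frequency
#'
#' Sorts the core symbols ascending by count. Ties are broken by the fixed
#' order A < C < G < T < N with the later symbol deemed less frequent, so the
#' ranking is deterministic; zero counts are allowed. The three rarest
#' symbols become grammar-rule codewords; the two commonest (the
#' highest-frequency symbol, HFS, and the second HFS) survive unchanged.
#'
#' @param freq named counts as returned by [count_frequencies()].
#' @return a list of class `grass_ranking` with elements `least`,
#'   `second_least`, `third_least`, `hfs`, `second_hfs`.
#' @export
rank_symbols <- function(freq) {
  stopifnot(all(CORE_SYMBOLS %in% names(freq)))
  counts <- as.numeric(freq[CORE_SYMBOLS])
  # ascending by count; on ties the later symbol in A<C<G<T<N ranks rarer
  o <- order(counts, -seq_along(CORE_SYMBOLS))
  sorted <- CORE_SYMBOLS[o]
  structure(
    list(least = sorted[1], second_least = sorted[2], third_least = sorted[3],
         hfs = sorted[5], second_hfs = sorted[4]),
    class = "grass_ranking"
  )
}

#' @export
print.grass_ranking <- function(x, ...) {
  cat(sprintf("core symbol ranking: rare (%s, %s, %s) | common (%s > %s)\n",
              x$least, x$second_least, x$third_least, x$hfs, x$second_hfs))
  invisible(x)
}

ranking_to_vec <- function(ranking) {
  unlist(ranking[c("least", "second_least", "third_least", "hfs", "second_hfs")],
         use.names = FALSE)
}

vec_to_ranking <- function(v) {
  if (length(v) != 5 || !setequal(v, CORE_SYMBOLS)) {
    stop_corrupt("invalid symbol ranking")
  }
  structure(list(least = v[1], second_least = v[2], third_least = v[3],
                 hfs = v[4], second_hfs = v[5]),
            class = "grass_ranking")
}

#' Apply grammar rule 1: expand the three rarest symbols
#'
#' Rewrites the least frequent symbol as `ZZ`, the second least as
#' `Z` + HFS and the third least as `Z` + second HFS; the HFS and second HFS
#' pass through unchanged. The output alphabet is `{HFS, second HFS, Z}` and
#' the codeword set is prefix-free, so the expansion is uniquely decodable.
#'
#' @param core string over the core alphabet.
#' @param ranking a `grass_ranking`.
#' @return the expanded string, of length `2*(l + s_l + t_l) + o_l` where
#'   l, s_l, t_l are the three smallest counts and o_l the sum of the other
#'   two (see [expanded_length()]).
#' @export
apply_rule1 <- function(core, ranking) {
  stopifnot(inherits(ranking, "grass_ranking"))
  # replacements never contain the rare source symbols, so sequential
  # fixed-string substitution cannot rewrite its own output
  x <- gsub(ranking$least, "ZZ", core, fixed = TRUE)
  x <- gsub(ranking$second_least, paste0("Z", ranking$hfs), x, fixed = TRUE)
  gsub(ranking$third_least, paste0("Z", ranking$second_hfs), x, fixed = TRUE)
}

#' Invert grammar rule 1
#'
#' Left-to-right decode of the expanded stream: a bare HFS / second-HFS
#' symbol stands for itself; `Z` always opens a two-character codeword
#' (`ZZ`, `Z`+HFS, `Z`+second HFS for the three rare symbols).
#'
#' @param expanded string over `{HFS, second HFS, Z}`.
#' @inheritParams apply_rule1
#' @return the original core string.
#' @export
invert_rule1 <- function(expanded, ranking) {
  stopifnot(inherits(ranking, "grass_ranking"))
  if (nchar(expanded) == 0) return("")
  ints <- utf8ToInt(expanded)
  zc <- utf8ToInt("Z")
  hfs <- utf8ToInt(ranking$hfs)
  shfs <- utf8ToInt(ranking$second_hfs)
  if (!all(ints %in% c(zc, hfs, shfs))) {
    stop_corrupt("expanded stream contains a symbol outside {HFS, second HFS, Z}")
  }
  isz <- ints == zc
  # Codewords parse greedily, so inside each maximal run of Z's the odd
  # positions open codewords. An odd-length run at end of input is dangling.
  runs <- rle(isz)
  within <- sequence(runs$lengths)
  starts <- which(isz & within %% 2L == 1L)
  if (length(starts) > 0 && starts[length(starts)] == length(ints)) {
    stop_corrupt("dangling flag symbol at end of stream")
  }
  partners <- starts + 1L
  partner_sym <- ints[partners]
  decoded_rare <- character(length(starts))
  decoded_rare[partner_sym == zc] <- ranking$least
  decoded_rare[partner_sym == hfs] <- ranking$second_least
  decoded_rare[partner_sym == shfs] <- ranking$third_least
  bare <- setdiff(which(!isz), partners)
  pos <- c(starts, bare)
  sym <- c(decoded_rare, intToUtf8(ints[bare], multiple = TRUE))
  paste(sym[order(pos)], collapse = "")
}

#' Substitute digits for the three surviving symbols
#'
#' Relabels the expanded stream as digits: HFS becomes `0`, second HFS `1`,
#' and the flag `Z` becomes `2`.
#'
#' @inheritParams invert_rule1
#' @return a digit string over `{0,1,2}`.
#' @export
apply_substitution <- function(expanded, ranking) {
  stopifnot(inherits(ranking, "grass_ranking"))
  if (nchar(expanded) > 0) {
    ints <- utf8ToInt(expanded)
    ok <- utf8ToInt(paste0(ranking$hfs, ranking$second_hfs, "Z"))
    if (!all(ints %in% ok)) {
      grass_error("expanded stream contains an unexpected symbol", "grass_internal")
    }
  }
  chartr(paste0(ranking$hfs, ranking$second_hfs, "Z"), "012", expanded)
}

#' @rdname apply_substitution
#' @param digits a digit string over `{0,1,2}`.
#' @export
invert_substitution <- function(digits, ranking) {
  stopifnot(inherits(ranking, "grass_ranking"))
  chartr("012", paste0(ranking$hfs, ranking$second_hfs, "Z"), digits)
}

#' Apply grammar rule 2: pair adjacent digits into nine symbols
#'
#' Maps non-overlapping digit pairs left to right through the fixed table
#' 00→P, 01→Q, 10→R, 02→S, 20→U, 11→V, 12→W, 21→X, 22→Y, halving the stream.
#' An odd trailing digit is carried separately rather than padded, so the
#' digit count is recovered exactly.
#'
#' @param digits a digit string over `{0,1,2}`.
#' @return list with `pairs` (string over P,Q,R,S,U,V,W,X,Y) and
#'   `trailing_digit` (single digit character or `NA`).
#' @export
pair_encode <- function(digits) {
  n <- nchar(digits)
  if (n == 0) return(list(pairs = "", trailing_digit = NA_character_))
  d <- utf8ToInt(digits) - 48L
  if (any(d < 0 | d > 2)) {
    grass_error("digit stream contains a symbol outside {0,1,2}", "grass_internal")
  }
  trailing <- if (n %% 2 == 1) substr(digits, n, n) else NA_character_
  if (n < 2) return(list(pairs = "", trailing_digit = trailing))
  m <- (n %/% 2) * 2
  a <- d[seq(1, m, by = 2)]
  b <- d[seq(2, m, by = 2)]
  list(pairs = paste(PAIR_SYMBOLS[3L * a + b + 1L], collapse = ""),
       trailing_digit = trailing)
}

#' @rdname pair_encode
#' @param pairs string over the nine pair symbols.
#' @param trailing_digit single digit character or `NA`.
#' @export
pair_decode <- function(pairs, trailing_digit = NA_character_) {
  tail <- if (is.na(trailing_digit)) "" else trailing_digit
  if (!tail %in% c("", "0", "1", "2")) stop_corrupt("invalid trailing digit")
  if (nchar(pairs) == 0) return(tail)
  idx <- match(strsplit(pairs, "", fixed = TRUE)[[1]], PAIR_SYMBOLS)
  if (anyNA(idx)) stop_corrupt("pair stream contains a symbol outside P..Y")
  code <- idx - 1L
  d <- integer(2L * length(code))
  d[c(TRUE, FALSE)] <- code %/% 3L
  d[c(FALSE, TRUE)] <- code %% 3L
  paste0(paste(d, collapse = ""), tail)
}

#' Expanded stream length from the frequency table
#'
#' The grammar-rule-1 output length follows from the counts alone: with l,
#' s_l, t_l the three smallest counts and o_l the sum of the two largest,
#' the expanded stream has `2*(l + s_l + t_l) + o_l` characters.
#'
#' @inheritParams rank_symbols
#' @return integer expanded length.
#' @export
expanded_length <- function(freq) {
  counts <- sort(as.numeric(freq[CORE_SYMBOLS]))
  sum(2 * counts[1:3]) + sum(counts[4:5])
}

# full encoding phase: core string -> pair stream + header fields
encode_core <- function(core) {
  freq <- count_frequencies(core)
  ranking <- rank_symbols(freq)
  expanded <- apply_rule1(core, ranking)
  stopifnot(nchar(expanded) == expanded_length(freq))
  digits <- apply_substitution(expanded, ranking)
  enc <- pair_encode(digits)
  list(pairs = enc$pairs, trailing_digit = enc$trailing_digit, ranking = ranking)
}

decode_core <- function(pairs, trailing_digit, ranking) {
  digits <- pair_decode(pairs, trailing_digit)
  expanded <- invert_substitution(digits, ranking)
  invert_rule1(expanded, ranking)
}
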