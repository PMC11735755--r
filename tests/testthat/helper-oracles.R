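# Independent oracles and small generators used across the suite. Nothing
# here calls the package's own decoders except where a test explicitly
# compares the two routes.

# random core stream over a (possibly degenerate) subset of the core alphabet
random_core <- function(max_len = 50, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- sample(c("A", "C", "G", "T", "N"), sample(1:5, 1))
  }
  n <- sample(0:max_len, 1)
  if (n == 0) "" else paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive parse counter for the rule-1 code {hfs, shfs, ZZ, Z+hfs, Z+shfs}
# over ALL 3-symbol strings of a given length, as a vectorized DP:
# ways_i = ways_{i-1} * [s_i != Z] + ways_{i-2} * [s_{i-1} == Z]
# (any of the three symbols is a valid second character after a flag Z).
# Returns the number of distinct decodings for every string of length L.
parse_count_all_strings <- function(L) {
  grids <- rep(list(c("H", "S", "Z")), L) # H = HFS, S = second HFS
  m <- as.matrix(expand.grid(grids, stringsAsFactors = FALSE))
  isz <- m == "Z"
  ways_prev2 <- rep(1, nrow(m)) # ways for empty prefix
  ways_prev1 <- as.numeric(!isz[, 1])
  if (L == 1) return(ways_prev1)
  for (i in 2:L) {
    ways <- ways_prev1 * as.numeric(!isz[, i]) + ways_prev2 * as.numeric(isz[, i - 1])
    ways_prev2 <- ways_prev1
    ways_prev1 <- ways
  }
  ways_prev1
}

# literal recursive brute-force decoder: every way to parse `s` into
# codewords, decoded; independent of invert_rule1
brute_decode_all <- function(s, ranking) {
  if (nchar(s) == 0) return(list(""))
  out <- list()
  c1 <- substr(s, 1, 1)
  if (c1 == ranking$hfs || c1 == ranking$second_hfs) {
    for (rest in brute_decode_all(substr(s, 2, nchar(s)), ranking)) {
      out <- c(out, list(paste0(c1, rest)))
    }
  }
  if (c1 == "Z" && nchar(s) >= 2) {
    c2 <- substr(s, 2, 2)
    sym <- if (c2 == "Z") ranking$least
           else if (c2 == ranking$hfs) ranking$second_least
           else if (c2 == ranking$second_hfs) ranking$third_least
           else NA_character_
    if (!is.na(sym)) {
      for (rest in brute_decode_all(substr(s, 3, nchar(s)), ranking)) {
        out <- c(out, list(paste0(sym, rest)))
      }
    }
  }
  out
}

# hand tally of symbol counts, independent of count_frequencies
tally_oracle <- function(core) {
  counts <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  if (nchar(core) > 0) {
    tab <- table(strsplit(core, "", fixed = TRUE)[[1]])
    counts[names(tab)] <- as.numeric(tab)
  }
  counts
}

example1_text <- function() example_fixtures()$example1$text
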