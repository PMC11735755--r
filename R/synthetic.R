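# Deterministic generator of synthetic sequence files, plus the two worked
# examples used as exact oracles throughout the test suite.

IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Generate a synthetic sequence file
#'
#' Produces well-formed raw / FASTA / multi-FASTA text with controllable
#' structure: record count, length range, base composition, special-character
#' (IUPAC ambiguity) rate, lowercase-run rate and mean run length, wrap
#' width, and DNA/RNA alphabet. Generation uses R's Mersenne-Twister RNG
#' under an explicit seed, so the same parameters always produce identical
#' bytes, without disturbing the caller's RNG state.
#'
#' @param record_count number of records (must be 1 for `format = "raw"`).
#' @param min_length,max_length per-record residue count range.
#' @param base_weights length-4 composition weights for A, C, G, T (or U).
#' @param special_rate per-position probability of an ambiguity character.
#' @param special_alphabet letters drawn for special positions.
#' @param lowercase_rate per-position probability that a lowercase run starts.
#' @param mean_run_length mean lowercase run length (geometric, minimum 1).
#' @param wrap_width line width; `NULL` writes each record on one line.
#' @param rna write U instead of T.
#' @param format `"raw"`, `"fasta"` or `"multifasta"`.
#' @param seed integer seed; fully determines the output.
#' @return raw vector of file bytes.
#' @export
generate_input <- function(record_count = 1, min_length = 100, max_length = 1000,
                           base_weights = c(0.25, 0.25, 0.25, 0.25),
                           special_rate = 0, special_alphabet = IUPAC_AMBIGUITY,
                           lowercase_rate = 0, mean_run_length = 5,
                           wrap_width = 60, rna = FALSE,
                           format = c("fasta", "multifasta", "raw"), seed = 1) {
  format <- match.arg(format)
  if (format == "raw" && record_count != 1) {
    grass_error("raw format holds exactly one record", "grass_param")
  }
  if (format == "multifasta" && record_count < 2) {
    grass_error("multi-FASTA needs at least two records", "grass_param")
  }
  if (format == "fasta" && record_count != 1) {
    grass_error("FASTA holds exactly one record; use multifasta", "grass_param")
  }
  if (special_rate < 0 || special_rate > 1 || lowercase_rate < 0 || lowercase_rate > 1) {
    grass_error("rates must lie in [0, 1]", "grass_param")
  }
  if (min_length < 1 || max_length < min_length) {
    grass_error("invalid length range", "grass_param")
  }
  bases <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  with_local_seed(seed, {
    recs <- vapply(seq_len(record_count), function(i) {
      n <- min_length + sample.int(max_length - min_length + 1L, 1) - 1L
      chars <- sample(bases, n, replace = TRUE, prob = base_weights)
      if (special_rate > 0) {
        hit <- which(stats::runif(n) < special_rate)
        chars[hit] <- sample(special_alphabet, length(hit), replace = TRUE)
      }
      if (lowercase_rate > 0) {
        starts <- which(stats::runif(n) < lowercase_rate)
        lens <- 1 + stats::rgeom(length(starts), prob = 1 / mean_run_length)
        mask <- logical(n)
        for (j in seq_along(starts)) {
          mask[starts[j]:min(n, starts[j] + lens[j] - 1)] <- TRUE
        }
        chars[mask] <- tolower(chars[mask])
      }
      seqtxt <- paste(chars, collapse = "")
      body <- if (is.null(wrap_width)) seqtxt else {
        starts <- seq(1, n, by = wrap_width)
        paste(substring(seqtxt, starts, pmin(starts + wrap_width - 1, n)),
              collapse = "\n")
      }
      if (format == "raw") body else paste0(">seq", i, " synthetic\n", body)
    }, character(1))
    charToRaw(paste0(paste(recs, collapse = "\n"), "\n"))
  })
}

#' Worked-example fixtures
#'
#' Returns the two small worked examples used as exact oracles: the
#' `example1` record (`seq1.fa`: header `>chr`, 58 residues wrapped at width
#' 25, containing lowercase runs and three `Y` ambiguity characters) with
#' its expected Phase-1 products, and the `example2` frequency table with
#' the expected ranking and transform-stage stream prefixes for Phase 2.
#'
#' @return named list with elements `example1` and `example2`.
#' @export
example_fixtures <- function() {
  seq58 <- "ATTGCATGTcgatggATGGggaAAAATCGataggatAGATTTTTAAAACCCNNNNYYY"
  wrapped <- paste(substring(seq58, c(1, 26, 51), c(25, 50, 58)), collapse = "\n")
  example1 <- list(
    text = paste0(">chr\n", wrapped, "\n"),
    identifier = ">chr",
    block_length = 58,
    line_lengths = c(25L, 25L, 8L),
    core = "ATTGCATGTCGATGGATGGGGAAAAATCGATAGGATAGATTTTTAAAACCCNNNN",
    case_runs = data.frame(gap = c(9, 4, 7), length = c(6, 3, 7)),
    specials = data.frame(gap = c(55, 1, 1), code = c(24L, 24L, 24L)),
    line_rle = data.frame(value = c(25, 8), rep = c(2, 1))
  )
  freq2 <- c(A = 50L, C = 14L, G = 10L, T = 80L, N = 4L)
  example2 <- list(
    freq = freq2,
    ranking = rank_symbols(freq2),  # least N, then G, C; HFS T, second A
    expanded_length = 186,
    added_characters = 28,
    step3_prefix = "ATTZTZAATZTT",
    step4_prefix = "1002021102",
    step5_prefix = "RSSVS"
  )
  list(example1 = example1, example2 = example2)
}
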