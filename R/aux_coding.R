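# Encoders for the auxiliary (F2) streams: delta coding for lowercase runs,
# special-character entries and block lengths, run-length encoding for line
# lengths, and serialization of the whole auxiliary payload with
# length-prefixed sections.

#' Delta-code lowercase runs
#'
#' Lowercase masking runs are stored as (gap, length) tuples: the first tuple
#' holds the absolute 0-based start, each later tuple the distance from the
#' END of the previous run to this run's start. Runs starting at 9, 19, 29
#' with lengths 6, 3, 7 therefore encode as (9,6), (4,3), (7,7).
#'
#' @param runs data.frame with columns `start` (0-based, strictly increasing)
#'   and `length` (positive); runs must not overlap.
#' @return data.frame with columns `gap` and `length`.
#' @export
encode_case_runs <- function(runs) {
  if (nrow(runs) == 0) return(data.frame(gap = numeric(0), length = numeric(0)))
  start <- as.numeric(runs$start)
  len <- as.numeric(runs$length)
  if (any(len < 1)) grass_error("case-run lengths must be positive", "grass_invalid_run")
  ends <- start + len
  if (nrow(runs) > 1 && any(start[-1] < ends[-length(ends)])) {
    grass_error("case runs overlap or are out of order", "grass_invalid_run")
  }
  data.frame(gap = c(start[1], start[-1] - ends[-length(ends)]), length = len)
}

#' @rdname encode_case_runs
#' @param coded data.frame with columns `gap` and `length`.
#' @export
decode_case_runs <- function(coded) {
  if (nrow(coded) == 0) return(data.frame(start = numeric(0), length = numeric(0)))
  gap <- as.numeric(coded$gap)
  len <- as.numeric(coded$length)
  if (any(gap < 0) || any(len < 1)) stop_corrupt("invalid case-run tuple")
  # start_i = gap_i + end_{i-1} = cumsum(gap)_i + cumsum(length)_{i-1}
  start <- cumsum(gap) + c(0, cumsum(len)[-length(len)])
  data.frame(start = start, length = len)
}

#' Delta-code special-character entries
#'
#' Special characters (any letter outside the record's core alphabet) are
#' stored as (gap, code) tuples: the first gap is the absolute 0-based
#' position, later gaps the difference from the previous special's position;
#' the code is the letter's 0-based index in the alphabet ('A' is 0, 'Y' 24).
#'
#' @param entries data.frame with columns `position` (0-based, strictly
#'   increasing) and `letter` (single uppercase letters).
#' @param core_alphabet letters that are NOT special for this record.
#' @return data.frame with columns `gap` and `code`.
#' @export
encode_specials <- function(entries, core_alphabet = c("A", "C", "G", "T", "N")) {
  if (nrow(entries) == 0) return(data.frame(gap = numeric(0), code = integer(0)))
  pos <- as.numeric(entries$position)
  letter <- as.character(entries$letter)
  if (any(diff(pos) <= 0)) {
    grass_error("special positions must be strictly increasing", "grass_invalid_special")
  }
  if (any(letter %in% core_alphabet)) {
    grass_error("core-alphabet letter recorded as special", "grass_invalid_special")
  }
  code <- match(letter, LETTERS) - 1L
  if (anyNA(code)) {
    grass_error("special characters must be uppercase letters", "grass_invalid_special")
  }
  data.frame(gap = c(pos[1], diff(pos)), code = code)
}

#' @rdname encode_specials
#' @param coded data.frame with columns `gap` and `code`.
#' @export
decode_specials <- function(coded) {
  if (nrow(coded) == 0) return(data.frame(position = numeric(0), letter = character(0)))
  gap <- as.numeric(coded$gap)
  code <- as.integer(coded$code)
  if (any(gap < 0) || gap[1] < 0 || any(gap[-1] < 1) || any(code < 0 | code > 25)) {
    stop_corrupt("invalid special-character tuple")
  }
  data.frame(position = cumsum(gap), letter = LETTERS[code + 1L])
}

#' Run-length encode line lengths
#'
#' FASTA layout usually wraps at one width with a short last line, so line
#' lengths compress to a handful of (value, repeat) pairs over maximal runs.
#'
#' @param lengths vector of positive line lengths.
#' @return data.frame with columns `value` and `rep`.
#' @export
rle_line_lengths <- function(lengths) {
  if (length(lengths) == 0) return(data.frame(value = numeric(0), rep = numeric(0)))
  if (any(lengths < 1)) grass_error("line lengths must be positive", "grass_invalid_layout")
  r <- rle(as.numeric(lengths))
  data.frame(value = r$values, rep = r$lengths)
}

#' @rdname rle_line_lengths
#' @param pairs data.frame with columns `value` and `rep`.
#' @export
unrle_line_lengths <- function(pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  if (any(pairs$value < 1) || any(pairs$rep < 1)) stop_corrupt("invalid line-length pair")
  rep(as.numeric(pairs$value), as.numeric(pairs$rep))
}

#' Delta-code block lengths
#'
#' Per-record block (residue-count) lengths are stored as the first value
#' followed by successive differences; differences may be negative and are
#' zig-zag mapped when serialized.
#'
#' @param lengths vector of positive block lengths.
#' @return numeric vector of deltas (first element absolute).
#' @export
delta_block_lengths <- function(lengths) {
  if (length(lengths) == 0) return(numeric(0))
  c(lengths[1], diff(as.numeric(lengths)))
}

#' @rdname delta_block_lengths
#' @param deltas numeric vector as produced by [delta_block_lengths()].
#' @export
undelta_block_lengths <- function(deltas) {
  if (length(deltas) == 0) return(numeric(0))
  out <- cumsum(as.numeric(deltas))
  if (any(out < 1)) stop_corrupt("decoded block length is not positive")
  out
}

# --- serialization of the full auxiliary payload ---
# layout: n_records, then length-prefixed sections in fixed order:
# identifiers, case runs, specials, line RLE, block deltas, flags.

wrap_section <- function(body) c(varint_encode(length(body)), body)

read_section <- function(reader) {
  n <- read_varint(reader)
  new_reader(read_bytes(reader, n))
}

close_section <- function(sec) {
  if (reader_remaining(sec) != 0) stop_corrupt("auxiliary section has trailing bytes")
}

encode_aux <- function(aux) {
  n_rec <- length(aux$block_deltas)
  ids <- c(varint_encode(length(aux$identifiers)),
           unlist(lapply(aux$identifiers, function(id) {
             b <- charToRaw(id)
             c(varint_encode(length(b)), b)
           }), use.names = FALSE))
  if (is.null(ids)) ids <- varint_encode(0)

  cr_counts <- vapply(aux$case_runs, nrow, integer(1))
  cr <- c(varint_encode(cr_counts),
          varint_encode(unlist(lapply(aux$case_runs, `[[`, "gap"), use.names = FALSE)),
          entropy_encode_values(unlist(lapply(aux$case_runs, `[[`, "length"), use.names = FALSE)))

  sp_counts <- vapply(aux$specials, nrow, integer(1))
  sp <- c(varint_encode(sp_counts),
          varint_encode(unlist(lapply(aux$specials, `[[`, "gap"), use.names = FALSE)),
          entropy_encode_values(unlist(lapply(aux$specials, `[[`, "code"), use.names = FALSE)))

  lr_counts <- vapply(aux$line_rle, nrow, integer(1))
  lr <- c(varint_encode(lr_counts),
          varint_encode(unlist(lapply(aux$line_rle, `[[`, "value"), use.names = FALSE)),
          varint_encode(unlist(lapply(aux$line_rle, `[[`, "rep"), use.names = FALSE)))

  bd <- varint_encode(zigzag_encode(aux$block_deltas))

  fl <- if (n_rec > 0) pack_bitvec(as.integer(aux$rna_flags)) else raw(0)

  c(varint_encode(n_rec),
    wrap_section(ids), wrap_section(cr), wrap_section(sp),
    wrap_section(lr), wrap_section(bd), wrap_section(fl))
}

decode_aux <- function(bytes) {
  r <- new_reader(bytes)
  n_rec <- read_varint(r)

  sec <- read_section(r)
  n_ids <- read_varint(sec)
  identifiers <- vapply(seq_len(n_ids), function(i) {
    rawToChar(read_bytes(sec, read_varint(sec)))
  }, character(1))
  close_section(sec)

  sec <- read_section(r)
  cr_counts <- read_varints(sec, n_rec)
  cr_gaps <- read_varints(sec, sum(cr_counts))
  cr_lens <- entropy_decode_values(sec)
  close_section(sec)
  if (length(cr_lens) != sum(cr_counts)) stop_corrupt("case-run stream length mismatch")
  f <- rep(seq_len(n_rec), cr_counts)
  case_runs <- lapply(seq_len(n_rec), function(i) {
    data.frame(gap = cr_gaps[f == i], length = cr_lens[f == i])
  })

  sec <- read_section(r)
  sp_counts <- read_varints(sec, n_rec)
  sp_gaps <- read_varints(sec, sum(sp_counts))
  sp_codes <- entropy_decode_values(sec)
  close_section(sec)
  if (length(sp_codes) != sum(sp_counts)) stop_corrupt("special stream length mismatch")
  f <- rep(seq_len(n_rec), sp_counts)
  specials <- lapply(seq_len(n_rec), function(i) {
    data.frame(gap = sp_gaps[f == i], code = as.integer(sp_codes[f == i]))
  })

  sec <- read_section(r)
  lr_counts <- read_varints(sec, n_rec)
  lr_vals <- read_varints(sec, sum(lr_counts))
  lr_reps <- read_varints(sec, sum(lr_counts))
  close_section(sec)
  f <- rep(seq_len(n_rec), lr_counts)
  line_rle <- lapply(seq_len(n_rec), function(i) {
    data.frame(value = lr_vals[f == i], rep = lr_reps[f == i])
  })

  sec <- read_section(r)
  block_deltas <- zigzag_decode(read_varints(sec, n_rec))
  close_section(sec)

  sec <- read_section(r)
  rna_flags <- if (n_rec > 0) {
    bits <- unpack_bitvec(read_bytes(sec, ceiling(n_rec / 8)))
    as.logical(bits[seq_len(n_rec)])
  } else logical(0)
  close_section(sec)

  if (reader_remaining(r) != 0) stop_corrupt("auxiliary payload has trailing bytes")

  list(identifiers = identifiers, case_runs = case_runs, specials = specials,
       line_rle = line_rle, block_deltas = block_deltas, rna_flags = rna_flags)
}
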