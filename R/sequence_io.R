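# Phase 1: parse raw / FASTA / multi-FASTA input, separate the core
# nucleotide stream (F1) from auxiliary data (F2), and reconstruct the
# original bytes exactly on decode.

as_input_bytes <- function(input) {
  if (is.raw(input)) return(input)
  if (is.character(input) && length(input) == 1) return(charToRaw(input))
  grass_error("input must be a raw vector or a single string", "grass_param")
}

#' Detect the input format
#'
#' @param input raw vector (or single string) of file content.
#' @return `"fasta"` if exactly one line starts with `>`, `"multifasta"` if
#'   two or more do, `"raw"` otherwise.
#' @export
detect_format <- function(input) {
  bytes <- as_input_bytes(input)
  if (length(bytes) == 0) grass_error("input is empty", "grass_empty_input")
  nl <- bytes == as.raw(10L)
  at_line_start <- c(TRUE, nl[-length(nl)])
  n_headers <- sum(at_line_start & bytes == charToRaw(">"))
  if (n_headers == 0) "raw" else if (n_headers == 1) "fasta" else "multifasta"
}

#' Parse a sequence file into records
#'
#' Splits the input into records with verbatim identifier lines and per-line
#' layout, normalizing line endings to LF internally. The parse retains
#' everything needed to reproduce the input byte-for-byte: per-record line
#' lengths, the EOL style (LF or CRLF) and whether a final newline was
#' present.
#'
#' @inheritParams detect_format
#' @return list with `records` (each a list with `identifier` — `NA` for raw
#'   input — `residues` and `line_lengths`), `format`, `eol` (`"lf"` or
#'   `"crlf"`) and `final_newline`.
#' @export
parse_input <- function(input) {
  bytes <- as_input_bytes(input)
  fmt <- detect_format(bytes)

  cr <- as.raw(13L); lf <- as.raw(10L)
  eol <- "lf"
  if (any(bytes == cr)) {
    n_cr <- sum(bytes == cr)
    crlf <- sum(bytes[-length(bytes)] == cr & bytes[-1] == lf)
    if (n_cr != crlf) {
      grass_error("stray carriage return outside a CRLF line ending", "grass_unsupported_byte")
    }
    eol <- "crlf"
    bytes <- bytes[bytes != cr]
  }
  if (any(bytes != lf & (bytes < as.raw(32L) | bytes > as.raw(126L)))) {
    grass_error("input contains non-printable or non-ASCII bytes", "grass_unsupported_byte")
  }
  final_newline <- bytes[length(bytes)] == lf
  text <- rawToChar(bytes)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (final_newline && length(lines) > 0 && text == paste0(paste(lines, collapse = "\n"), "\n")) {
    # strsplit drops the final empty piece; nothing to fix
  }
  if (any(nchar(lines) == 0)) {
    grass_error("empty lines are not supported", "grass_malformed_input")
  }

  is_header <- startsWith(lines, ">")
  if (fmt == "raw") {
    body <- lines
    if (any(grepl(">", body, fixed = TRUE))) {
      grass_error("'>' inside a sequence line", "grass_malformed_fasta")
    }
    check_residue_lines(body)
    records <- list(list(identifier = NA_character_,
                         residues = paste(body, collapse = ""),
                         line_lengths = nchar(body)))
  } else {
    if (!is_header[1]) {
      grass_error("FASTA input must start with a '>' header line", "grass_malformed_fasta")
    }
    if (any(grepl(">", lines[!is_header], fixed = TRUE))) {
      grass_error("'>' inside a sequence line", "grass_malformed_fasta")
    }
    rec_id <- cumsum(is_header)
    records <- lapply(seq_len(max(rec_id)), function(i) {
      chunk <- lines[rec_id == i]
      body <- chunk[-1]
      if (length(body) == 0) {
        grass_error("record has a header but no sequence lines", "grass_malformed_fasta")
      }
      check_residue_lines(body)
      list(identifier = chunk[1],
           residues = paste(body, collapse = ""),
           line_lengths = nchar(body))
    })
  }
  list(records = records, format = fmt, eol = eol, final_newline = final_newline)
}

check_residue_lines <- function(lines) {
  if (any(!grepl("^[A-Za-z]+$", lines))) {
    grass_error("sequence lines may contain letters only", "grass_unsupported_byte")
  }
}

record_core_alphabet <- function(residues_upper) {
  # a record written with U and no T is RNA: U joins the core alphabet and
  # occupies the T slot downstream; a record mixing T and U keeps U special
  has_u <- grepl("U", residues_upper, fixed = TRUE)
  has_t <- grepl("T", residues_upper, fixed = TRUE)
  rna <- has_u && !has_t
  list(rna = rna, alphabet = if (rna) c("A", "C", "G", "U", "N") else c("A", "C", "G", "T", "N"))
}

#' Separate the core nucleotide stream from auxiliary data
#'
#' Case-folds each record to uppercase, records lowercase runs as delta-coded
#' (gap, length) tuples over the full pre-removal coordinates, removes every
#' letter outside the record's five-symbol core alphabet and records it as a
#' delta-coded (gap, letter-code) tuple, and keeps the per-record layout
#' (line-length RLE, block lengths). The count identity
#' `n_tar = n_seq - n_spl` holds per record and in total.
#'
#' @param parsed result of [parse_input()].
#' @return list with `core` (concatenated core stream; RNA records keep `U`),
#'   `aux` (auxiliary streams), and the per-record counts `n_seq`, `n_spl`
#'   plus total `n_tar`.
#' @export
extract_streams <- function(parsed) {
  records <- parsed$records
  n_rec <- length(records)
  cores <- character(n_rec)
  case_runs <- vector("list", n_rec)
  specials <- vector("list", n_rec)
  line_rle <- vector("list", n_rec)
  rna_flags <- logical(n_rec)
  n_seq <- numeric(n_rec)
  n_spl <- numeric(n_rec)

  for (i in seq_len(n_rec)) {
    res <- records[[i]]$residues
    n_seq[i] <- nchar(res)
    ints <- utf8ToInt(res)
    lower <- ints >= 97L & ints <= 122L
    r <- rle(lower)
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths          # 0-based run starts
    runs <- data.frame(start = starts0[r$values], length = r$lengths[r$values])
    case_runs[[i]] <- encode_case_runs(runs)

    upper <- ifelse(lower, ints - 32L, ints)
    up_chars <- intToUtf8(upper, multiple = TRUE)
    ca <- record_core_alphabet(intToUtf8(upper))
    rna_flags[i] <- ca$rna
    is_special <- !(up_chars %in% ca$alphabet)
    specials[[i]] <- encode_specials(
      data.frame(position = which(is_special) - 1, letter = up_chars[is_special]),
      core_alphabet = ca$alphabet
    )
    n_spl[i] <- sum(is_special)
    cores[i] <- intToUtf8(upper[!is_special])
    line_rle[[i]] <- rle_line_lengths(records[[i]]$line_lengths)
  }

  ids <- vapply(records, `[[`, character(1), "identifier")
  aux <- list(
    identifiers = if (parsed$format == "raw") character(0) else ids,
    case_runs = case_runs,
    specials = specials,
    line_rle = line_rle,
    block_deltas = delta_block_lengths(n_seq),
    rna_flags = rna_flags,
    eol = parsed$eol,
    final_newline = parsed$final_newline
  )
  list(core = paste(cores, collapse = ""), aux = aux,
       n_seq = n_seq, n_spl = n_spl, n_tar = sum(n_seq) - sum(n_spl))
}

#' Reconstruct the original file bytes from core and auxiliary streams
#'
#' Exact inverse of [extract_streams()] composed with [parse_input()]:
#' reinserts special characters at their absolute positions, restores
#' lowercase runs, rewraps lines, prepends identifier lines, and reapplies
#' the EOL style and final-newline state.
#'
#' @param core the concatenated core stream.
#' @param aux auxiliary streams as produced by [extract_streams()].
#' @return raw vector equal to the original input bytes.
#' @export
restore_records <- function(core, aux) {
  block_lengths <- undelta_block_lengths(aux$block_deltas)
  n_rec <- length(block_lengths)
  if (length(aux$identifiers) > 0 && length(aux$identifiers) != n_rec) {
    stop_corrupt("identifier count does not match record count")
  }
  sp <- lapply(aux$specials, decode_specials)
  n_spl <- vapply(sp, nrow, integer(1))
  core_lens <- block_lengths - n_spl
  if (any(core_lens < 0) || sum(core_lens) != nchar(core)) {
    stop_corrupt("block lengths inconsistent with core stream length")
  }
  core_ends <- cumsum(core_lens)
  core_starts <- core_ends - core_lens + 1

  out_records <- character(n_rec)
  for (i in seq_len(n_rec)) {
    seg <- substr(core, core_starts[i], core_ends[i])
    if (aux$rna_flags[i]) seg <- chartr("T", "U", seg)
    n <- block_lengths[i]
    chars <- character(n)
    if (n_spl[i] > 0) {
      pos <- sp[[i]]$position + 1
      if (any(pos > n)) stop_corrupt("special position beyond block length")
      chars[pos] <- sp[[i]]$letter
      chars[-pos] <- if (core_lens[i] > 0) strsplit(seg, "", fixed = TRUE)[[1]] else character(0)
    } else if (n > 0) {
      chars <- strsplit(seg, "", fixed = TRUE)[[1]]
    }
    runs <- decode_case_runs(aux$case_runs[[i]])
    if (nrow(runs) > 0) {
      idx <- unlist(mapply(function(s, l) seq(s + 1, s + l), runs$start, runs$length,
                           SIMPLIFY = FALSE), use.names = FALSE)
      if (max(idx) > n) stop_corrupt("lowercase run beyond block length")
      chars[idx] <- tolower(chars[idx])
    }
    lines_len <- unrle_line_lengths(aux$line_rle[[i]])
    if (sum(lines_len) != n) stop_corrupt("line lengths inconsistent with block length")
    stops <- cumsum(lines_len)
    starts <- stops - lines_len + 1
    body <- vapply(seq_along(lines_len), function(j) {
      paste(chars[starts[j]:stops[j]], collapse = "")
    }, character(1))
    id <- if (length(aux$identifiers) > 0) aux$identifiers[i] else NULL
    out_records[i] <- paste(c(id, body), collapse = "\n")
  }

  text <- paste(out_records, collapse = "\n")
  if (aux$final_newline) text <- paste0(text, "\n")
  if (identical(aux$eol, "crlf")) text <- gsub("\n", "\r\n", text, fixed = TRUE)
  charToRaw(text)
}
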