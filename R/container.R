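# Archive container and the pluggable parameter-free backend codec. The
# auxiliary (F2) and pair-symbol (F3) payloads are compressed as two
# independent backend streams behind a fixed, versioned header. The default
# backend is bzip2, a BWT-family block compressor that takes no parameters;
# gzip is available as a dictionary-based alternate.

GRASS_MAGIC <- charToRaw("GrSS")
GRASS_VERSION <- 1L

BACKENDS <- data.frame(
  id = c(0L, 1L),
  name = c("bzip2", "gzip"),
  stringsAsFactors = FALSE
)

backend_id <- function(backend) {
  if (is.numeric(backend)) {
    if (!backend %in% BACKENDS$id) {
      grass_error(sprintf("unknown backend id %s", backend), "grass_config")
    }
    return(as.integer(backend))
  }
  i <- match(backend, BACKENDS$name)
  if (is.na(i)) {
    grass_error(sprintf("unknown backend '%s' (use %s)", backend,
                        paste(BACKENDS$name, collapse = ", ")), "grass_config")
  }
  BACKENDS$id[i]
}

#' Backend byte compressors
#'
#' The final stage hands both payloads to a parameter-free general-purpose
#' codec. Backend 0 (`"bzip2"`) is the default: a block-sorting (BWT-family)
#' compressor. Backend 1 (`"gzip"`) is a dictionary-based alternate. Both are
#' lossless for arbitrary byte strings and expose no tuning parameters here.
#'
#' @param bytes raw vector.
#' @param backend backend id (0, 1) or name (`"bzip2"`, `"gzip"`).
#' @return raw vector.
#' @export
backend_compress <- function(bytes, backend = "bzip2") {
  id <- backend_id(backend)
  memCompress(bytes, type = BACKENDS$name[id + 1L])
}

#' @rdname backend_compress
#' @export
backend_decompress <- function(bytes, backend = "bzip2") {
  id <- backend_id(backend)
  memDecompress(bytes, type = BACKENDS$name[id + 1L])
}

eol_byte <- function(eol) if (identical(eol, "crlf")) 1L else 0L
format_byte <- function(fmt) match(fmt, c("raw", "fasta", "multifasta")) - 1L

#' Write a compressed archive
#'
#' Serializes the auxiliary streams and the pair-symbol stream, compresses
#' each with the chosen backend, and frames them with a fixed header: magic,
#' version, backend id, format tag, the stored symbol ranking, the trailing
#' digit, EOL and final-newline flags, and an Adler-32 checksum of the
#' original input for end-to-end verification.
#'
#' @param streams list with `aux` (auxiliary streams) and `pairs` (the pair
#'   symbol string).
#' @param ranking a `grass_ranking` (stored so the decoder never re-derives it).
#' @param trailing_digit single digit character or `NA`.
#' @param format_tag `"raw"`, `"fasta"` or `"multifasta"`.
#' @param checksum Adler-32 of the original input bytes.
#' @param backend backend id or name (see [backend_compress()]).
#' @return raw vector: the archive bytes.
#' @export
write_archive <- function(streams, ranking, trailing_digit, format_tag,
                          checksum, backend = "bzip2") {
  id <- backend_id(backend)
  aux_bytes <- encode_aux(streams$aux)
  pair_bytes <- charToRaw(streams$pairs)
  aux_c <- backend_compress(aux_bytes, id)
  pair_c <- backend_compress(pair_bytes, id)
  trailing <- if (is.na(trailing_digit)) 255L else as.integer(trailing_digit)
  c(GRASS_MAGIC,
    as.raw(GRASS_VERSION),
    as.raw(id),
    as.raw(format_byte(format_tag)),
    charToRaw(paste(ranking_to_vec(ranking), collapse = "")),
    as.raw(trailing),
    as.raw(eol_byte(streams$aux$eol)),
    as.raw(as.integer(isTRUE(streams$aux$final_newline))),
    u32_to_bytes(checksum),
    varint_encode(length(aux_c)), aux_c,
    varint_encode(length(pair_c)), pair_c)
}

#' Read a compressed archive
#'
#' Validates magic and version before touching any payload, then
#' decompresses and deserializes both payloads. Exact inverse of
#' [write_archive()].
#'
#' @param bytes raw vector: archive content.
#' @return list with `aux`, `pairs`, `ranking`, `trailing_digit`,
#'   `format_tag`, `checksum`, `backend`.
#' @export
read_archive <- function(bytes) {
  r <- new_reader(bytes)
  if (reader_remaining(r) < 18) {
    grass_error("not a grass archive (too short)", "grass_not_archive")
  }
  if (!identical(read_bytes(r, 4), GRASS_MAGIC)) {
    grass_error("not a grass archive (bad magic)", "grass_not_archive")
  }
  version <- as.integer(read_bytes(r, 1))
  if (version > GRASS_VERSION) {
    grass_error(sprintf("archive version %d is newer than supported (%d)",
                        version, GRASS_VERSION), "grass_version")
  }
  id <- as.integer(read_bytes(r, 1))
  if (!id %in% BACKENDS$id) grass_error("unknown backend id in archive", "grass_config")
  fmt <- c("raw", "fasta", "multifasta")[as.integer(read_bytes(r, 1)) + 1L]
  if (is.na(fmt)) grass_error("invalid format tag", "grass_corrupt_archive")
  ranking <- vec_to_ranking(strsplit(rawToChar(read_bytes(r, 5)), "", fixed = TRUE)[[1]])
  tr <- as.integer(read_bytes(r, 1))
  trailing <- if (tr == 255L) NA_character_ else as.character(tr)
  eol <- if (as.integer(read_bytes(r, 1)) == 1L) "crlf" else "lf"
  final_newline <- as.integer(read_bytes(r, 1)) == 1L
  checksum <- bytes_to_u32(read_bytes(r, 4))

  aux_c <- read_bytes(r, read_varint(r))
  pair_c <- read_bytes(r, read_varint(r))
  if (reader_remaining(r) != 0) {
    grass_error("trailing bytes after archive payloads", "grass_corrupt_archive")
  }
  aux <- tryCatch(decode_aux(backend_decompress(aux_c, id)), error = function(e) {
    grass_error(paste("corrupt auxiliary payload:", conditionMessage(e)),
                "grass_corrupt_archive")
  })
  pairs <- tryCatch(rawToChar(backend_decompress(pair_c, id)), error = function(e) {
    grass_error("corrupt pair-symbol payload", "grass_corrupt_archive")
  })
  aux$eol <- eol
  aux$final_newline <- final_newline
  list(aux = aux, pairs = pairs, ranking = ranking, trailing_digit = trailing,
       format_tag = fmt, checksum = checksum, backend = BACKENDS$name[id + 1L])
}

#' Compress a sequence file
#'
#' Runs the full two-phase pipeline: Phase 1 separates identifiers, case
#' runs, special characters and layout from the core A/C/G/T-or-U/N stream;
#' Phase 2 ranks the core symbols by frequency, applies the grammar and
#' substitution rules, pairs the digits, and hands both payloads to the
#' backend. Decompression with [grass_decompress()] is byte-exact.
#'
#' @param input path to a file, or raw vector / single string of content.
#' @param output optional path to write the archive to.
#' @param backend backend id or name (see [backend_compress()]).
#' @return raw vector of archive bytes, invisibly when `output` is given.
#' @examples
#' arc <- grass_compress(">chr1\nACGTacgtNNRY\nACGT\n")
#' rawToChar(grass_decompress(arc))
#' @export
grass_compress <- function(input, output = NULL, backend = "bzip2") {
  bytes <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    readBin(input, raw(), n = file.size(input))
  } else {
    as_input_bytes(input)
  }
  t0 <- proc.time()[["elapsed"]]
  parsed <- parse_input(bytes)
  ext <- extract_streams(parsed)
  grass_log("debug", "phase 1: %d record(s), n_tar=%d", length(parsed$records), ext$n_tar)
  core_dna <- chartr("U", "T", ext$core)  # U occupies the T slot in phase 2
  enc <- encode_core(core_dna)
  archive <- write_archive(
    streams = list(aux = ext$aux, pairs = enc$pairs),
    ranking = enc$ranking,
    trailing_digit = enc$trailing_digit,
    format_tag = parsed$format,
    checksum = adler32(bytes),
    backend = backend
  )
  grass_log("info", "compressed %d -> %d bytes (%.2fx) in %.3fs",
            length(bytes), length(archive), length(bytes) / length(archive),
            proc.time()[["elapsed"]] - t0)
  if (!is.null(output)) {
    writeBin(archive, output)
    return(invisible(archive))
  }
  archive
}

#' Decompress a grass archive
#'
#' Inverts every encoding stage in reverse order and verifies the stored
#' checksum of the original input, failing loudly on any corruption.
#'
#' @param input path to an archive, or raw vector of archive bytes.
#' @param output optional path to write the restored file to.
#' @return raw vector of the original file bytes, invisibly when `output`
#'   is given.
#' @export
grass_decompress <- function(input, output = NULL) {
  bytes <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    readBin(input, raw(), n = file.size(input))
  } else if (is.raw(input)) {
    input
  } else {
    grass_error("input must be an existing file or a raw vector", "grass_param")
  }
  t0 <- proc.time()[["elapsed"]]
  arc <- read_archive(bytes)
  core <- decode_core(arc$pairs, arc$trailing_digit, arc$ranking)
  restored <- restore_records(core, arc$aux)
  if (adler32(restored) != arc$checksum) {
    grass_error("checksum mismatch after decompression", "grass_corrupt_archive")
  }
  grass_log("info", "decompressed %d -> %d bytes in %.3fs",
            length(bytes), length(restored), proc.time()[["elapsed"]] - t0)
  if (!is.null(output)) {
    writeBin(restored, output)
    return(invisible(restored))
  }
  restored
}

#' Verify a round trip
#'
#' Compresses the input, decompresses the archive, and byte-compares the
#' result with the original.
#'
#' @inheritParams grass_compress
#' @return `TRUE` invisibly on success; errors on mismatch.
#' @export
grass_verify <- function(input, backend = "bzip2") {
  bytes <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    readBin(input, raw(), n = file.size(input))
  } else {
    as_input_bytes(input)
  }
  restored <- grass_decompress(grass_compress(bytes, backend = backend))
  if (!identical(restored, bytes)) {
    grass_error("round trip did not reproduce the input", "grass_verify_failed")
  }
  invisible(TRUE)
}
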