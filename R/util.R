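# Low-level helpers shared across the codec: structured errors, variable-length
# integers, zig-zag mapping, bit packing, Adler-32, and a byte-cursor reader.

grass_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "grass_error", "error", "condition")))
}

stop_corrupt <- function(msg) grass_error(msg, "grass_corrupt_stream")

#' @keywords internal
grass_log <- function(level, msg, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  want <- getOption("grassr.log_level", "warn")
  if (levels[[level]] >= levels[[want]]) {
    message(sprintf("[%s] %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%OS3"), sprintf(msg, ...)))
  }
  invisible(NULL)
}

# --- variable-length base-128 integers (LSB groups first, MSB = continue) ---

varint_encode <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) return(raw(0))
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    grass_error("varint values must be non-negative integers", "grass_internal")
  }
  if (all(x < 128)) return(as.raw(x))
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    b <- integer(0)
    repeat {
      lo <- v %% 128
      v <- (v - lo) / 128
      if (v > 0) b <- c(b, lo + 128) else { b <- c(b, lo); break }
    }
    out[[i]] <- b
  }
  as.raw(unlist(out, use.names = FALSE))
}

# zig-zag: signed -> non-negative, preserving small magnitudes
zigzag_encode <- function(x) 2 * abs(x) - (x < 0)
zigzag_decode <- function(z) {
  s <- z %% 2
  ((z + s) / 2) * (1 - 2 * s)
}

# --- byte cursor over a raw vector ---

new_reader <- function(bytes) {
  r <- new.env(parent = emptyenv())
  r$b <- bytes
  r$pos <- 1L
  r
}

reader_remaining <- function(r) length(r$b) - r$pos + 1L

read_bytes <- function(r, n) {
  n <- as.integer(n)
  if (n < 0 || reader_remaining(r) < n) stop_corrupt("truncated payload")
  v <- if (n == 0) raw(0) else r$b[r$pos:(r$pos + n - 1L)]
  r$pos <- r$pos + n
  v
}

read_varint <- function(r) {
  v <- 0
  mult <- 1
  repeat {
    if (reader_remaining(r) < 1L) stop_corrupt("truncated varint")
    byte <- as.integer(r$b[r$pos])
    r$pos <- r$pos + 1L
    v <- v + (byte %% 128) * mult
    if (byte < 128) return(v)
    mult <- mult * 128
  }
}

read_varints <- function(r, n) {
  if (n == 0) return(numeric(0))
  vapply(seq_len(n), function(i) read_varint(r), numeric(1))
}

# --- bit packing (bit order matches packBits/rawToBits on logicals) ---

pack_bitvec <- function(bits) {
  if (length(bits) == 0) return(raw(0))
  pad <- (-length(bits)) %% 8
  packBits(as.logical(c(bits, rep(0L, pad))))
}

unpack_bitvec <- function(bytes) as.integer(rawToBits(bytes))

# --- Adler-32 checksum, chunked so the weighted sum stays inside double ---

adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1; b <- 0
  n <- length(bytes)
  chunk <- 65536L
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    v <- as.integer(bytes[i:j])
    m <- length(v)
    # b accumulates the running value of a after every byte
    b <- (b + m * a + sum(as.numeric(m - seq_len(m) + 1) * v)) %% MOD
    a <- (a + sum(as.numeric(v))) %% MOD
    i <- j + 1L
  }
  b * 65536 + a
}

u32_to_bytes <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

bytes_to_u32 <- function(b) {
  v <- as.numeric(b)
  v[1] + v[2] * 256 + v[3] * 65536 + v[4] * 16777216
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
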