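# Evaluation metrics: per-file compression ratio (CR), corpus weighted
# average compression ratio (WACR) and compression-ratio improvement
# percentage (CRIP) against a baseline, plus a small benchmarking driver.

#' Compression ratio
#'
#' `CR = original size / compressed size`. Sizes are measured in bytes of
#' the on-disk files. A ratio below 1 means the file expanded
#' (incompressible input).
#'
#' @param original_size,compressed_size positive sizes in bytes (vectorized).
#' @return numeric ratio(s).
#' @export
compression_ratio <- function(original_size, compressed_size) {
  if (any(compressed_size <= 0)) {
    grass_error("compressed size must be positive", "grass_division")
  }
  original_size / compressed_size
}

#' Weighted average compression ratio over a corpus
#'
#' `WACR = total original size / total compressed size`, i.e. the per-file
#' ratios weighted by compressed size; it always lies between the smallest
#' and largest per-file CR.
#'
#' @param sizes data.frame with columns `original` and `compressed` (bytes).
#' @return numeric ratio.
#' @export
wacr <- function(sizes) {
  if (NROW(sizes) == 0) grass_error("empty corpus", "grass_empty_corpus")
  if (any(sizes$compressed <= 0)) {
    grass_error("compressed sizes must be positive", "grass_division")
  }
  sum(sizes$original) / sum(sizes$compressed)
}

#' Compression-ratio improvement percentage
#'
#' `CRIP = ((WACR_ours / WACR_baseline) - 1) * 100`, the relative WACR gain
#' over a comparison algorithm, in percent.
#'
#' @param wacr_ours,wacr_baseline positive WACR values.
#' @return numeric percentage.
#' @export
crip <- function(wacr_ours, wacr_baseline) {
  if (any(wacr_baseline <= 0)) {
    grass_error("baseline WACR must be positive", "grass_division")
  }
  (wacr_ours / wacr_baseline - 1) * 100
}

#' Benchmark compression over a set of files
#'
#' Compresses each file, records original and compressed sizes, per-file CR
#' and wall-clock seconds, and the corpus WACR. Optionally compares against
#' a gzip baseline via CRIP. Per-file CR is reported, never asserted:
#' incompressible inputs may expand.
#'
#' @param paths character vector of file paths, or a single directory.
#' @param backend backend id or name (see [backend_compress()]).
#' @param baseline `"none"` or `"gzip"` (whole-file gzip as comparison).
#' @return an object of class `grass_bench`: list with `files` (data.frame:
#'   file, original, compressed, cr, seconds), `wacr`, and when a baseline
#'   is requested `baseline_wacr` and `crip`.
#' @export
grass_bench <- function(paths, backend = "bzip2", baseline = c("none", "gzip")) {
  baseline <- match.arg(baseline)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  if (length(paths) == 0) grass_error("empty corpus", "grass_empty_corpus")
  rows <- lapply(paths, function(p) {
    bytes <- readBin(p, raw(), n = file.size(p))
    t0 <- proc.time()[["elapsed"]]
    arc <- grass_compress(bytes, backend = backend)
    secs <- proc.time()[["elapsed"]] - t0
    base_size <- if (baseline == "gzip") length(memCompress(bytes, type = "gzip")) else NA_real_
    data.frame(file = basename(p), original = length(bytes),
               compressed = length(arc),
               cr = compression_ratio(length(bytes), length(arc)),
               seconds = secs, baseline_compressed = base_size)
  })
  files <- do.call(rbind, rows)
  out <- list(files = files[, setdiff(names(files), "baseline_compressed")],
              wacr = wacr(data.frame(original = files$original,
                                     compressed = files$compressed)),
              backend = backend)
  if (baseline == "gzip") {
    out$baseline <- "gzip"
    out$baseline_wacr <- wacr(data.frame(original = files$original,
                                         compressed = files$baseline_compressed))
    out$crip <- crip(out$wacr, out$baseline_wacr)
  }
  class(out) <- "grass_bench"
  out
}

#' @export
print.grass_bench <- function(x, ...) {
  df <- x$files
  df$cr <- sprintf("%.2f", df$cr)
  df$seconds <- sprintf("%.3f", df$seconds)
  print(df, row.names = FALSE)
  cat(sprintf("WACR: %.2f (backend: %s)\n", x$wacr, x$backend))
  if (!is.null(x$crip)) {
    cat(sprintf("baseline %s WACR: %.2f, CRIP: %.2f%%\n",
                x$baseline, x$baseline_wacr, x$crip))
  }
  invisible(x)
}
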