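# Phase 1: parsing, stream separation, byte-exact restoration.

test_that("format detection distinguishes raw, FASTA and multi-FASTA", {
  expect_identical(detect_format(example1_text()), "fasta")
  expect_identical(detect_format("ACGT\n"), "raw")
  expect_identical(detect_format(">a\nAC\n>b\nGT\n"), "multifasta")
  expect_error(detect_format(raw(0)), class = "grass_empty_input")
})

test_that("parsing records identifiers, residues and per-line layout", {
  p <- parse_input(example1_text())
  expect_length(p$records, 1)
  expect_identical(p$records[[1]]$identifier, ">chr")
  expect_identical(nchar(p$records[[1]]$residues), 58L)
  expect_identical(p$records[[1]]$line_lengths, c(25L, 25L, 8L))

  p <- parse_input("ACGT") # raw, no final newline
  expect_true(is.na(p$records[[1]]$identifier))
  expect_identical(p$records[[1]]$line_lengths, 4L)
  expect_false(p$final_newline)

  p <- parse_input(">a\nACGT\nACG\n")
  expect_length(p$records, 1)
  expect_identical(p$records[[1]]$line_lengths, c(4L, 3L))
})

test_that("malformed and unsupported inputs are rejected", {
  expect_error(parse_input(">a\nAC>T\n"), class = "grass_malformed_fasta")
  expect_error(parse_input("AC>T\nGGG>\n"), class = "grass_malformed_fasta")
  expect_error(parse_input("AC\x01GT\n"), class = "grass_unsupported_byte")
  expect_error(parse_input("AC GT\n"), class = "grass_unsupported_byte")
  expect_error(parse_input("AC1GT\n"), class = "grass_unsupported_byte")
  expect_error(parse_input(">a\n\nACGT\n"), class = "grass_malformed_input")
  expect_error(parse_input(">a\n>b\nACGT\n"), class = "grass_malformed_fasta")
})

test_that("stream separation reproduces the worked example's auxiliary tuples", {
  fx <- example_fixtures()$example1
  ex <- extract_streams(parse_input(fx$text))
  expect_identical(ex$core, fx$core)
  expect_identical(nchar(ex$core), 55L)
  expect_equal(ex$aux$case_runs[[1]], fx$case_runs)
  expect_equal(ex$aux$specials[[1]], fx$specials)
  expect_equal(ex$aux$line_rle[[1]], fx$line_rle)
  expect_equal(undelta_block_lengths(ex$aux$block_deltas), fx$block_length)
  expect_equal(ex$n_tar, ex$n_seq - ex$n_spl)
  expect_equal(ex$n_tar, 55)
})

test_that("case folding and the first-run-absolute convention", {
  ex <- extract_streams(parse_input(">a\nACGTN\n"))
  expect_identical(nrow(ex$aux$case_runs[[1]]), 0L)
  expect_identical(nrow(ex$aux$specials[[1]]), 0L)
  expect_identical(ex$core, "ACGTN")

  ex <- extract_streams(parse_input("acgt\n"))
  expect_equal(ex$aux$case_runs[[1]], data.frame(gap = 0, length = 4))
  expect_identical(ex$core, "ACGT")
})

test_that("U/T handling: U-only records are RNA, mixed records keep U special", {
  ex <- extract_streams(parse_input(">r\nACGU\n"))
  expect_true(ex$aux$rna_flags[1])
  expect_identical(ex$core, "ACGU")
  expect_identical(ex$n_spl, 0)

  ex <- extract_streams(parse_input(">m\nACGTU\n"))
  expect_false(ex$aux$rna_flags[1])
  expect_identical(ex$core, "ACGT")
  expect_equal(decode_specials(ex$aux$specials[[1]])$letter, "U")
})

test_that("restoration is the exact inverse of extraction", {
  fx <- example_fixtures()$example1
  ex <- extract_streams(parse_input(fx$text))
  expect_identical(restore_records(ex$core, ex$aux), charToRaw(fx$text))

  empty_aux <- list(identifiers = character(0), case_runs = list(),
                    specials = list(), line_rle = list(),
                    block_deltas = numeric(0), rna_flags = logical(0),
                    eol = "lf", final_newline = FALSE)
  expect_identical(restore_records("", empty_aux), raw(0))
})

test_that("restoration rejects inconsistent stream lengths", {
  ex <- extract_streams(parse_input(example1_text()))
  expect_error(restore_records(substr(ex$core, 1, 10), ex$aux),
               class = "grass_corrupt_stream")
  bad <- ex$aux
  bad$line_rle[[1]] <- data.frame(value = 58, rep = 2)
  expect_error(restore_records(ex$core, bad), class = "grass_corrupt_stream")
})

test_that("extract/restore is the identity on 1000 generated records", {
  total_records <- 0
  i <- 0
  while (total_records < 1000) {
    i <- i + 1
    nrec <- sample(5:15, 1)
    bytes <- generate_input(
      record_count = nrec, min_length = 1, max_length = 120,
      special_rate = sample(c(0, 0.05, 0.4), 1),
      lowercase_rate = sample(c(0, 0.1, 0.6), 1),
      wrap_width = sample(c(1, 10, 60), 1),
      rna = i %% 3 == 0, format = "multifasta", seed = 5000 + i
    )
    p <- parse_input(bytes)
    ex <- extract_streams(p)
    expect_equal(ex$n_tar, sum(ex$n_seq) - sum(ex$n_spl))
    expect_identical(restore_records(ex$core, ex$aux), bytes)
    total_records <- total_records + nrec
  }
  expect_gte(total_records, 1000)
})

test_that("core stream alphabet stays inside the five-symbol core set", {
  for (i in 1:20) {
    bytes <- generate_input(record_count = 1, min_length = 50, max_length = 200,
                            special_rate = 0.3, lowercase_rate = 0.3,
                            rna = i %% 2 == 0, format = "fasta", seed = 400 + i)
    ex <- extract_streams(parse_input(bytes))
    chars <- unique(strsplit(ex$core, "", fixed = TRUE)[[1]])
    allowed <- if (any(ex$aux$rna_flags)) c("A", "C", "G", "T", "N", "U")
               else c("A", "C", "G", "T", "N")
    expect_true(all(chars %in% allowed))
    expect_false(any(chars %in% letters))
  }
})
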