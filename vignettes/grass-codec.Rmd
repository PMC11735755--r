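---
title: "A grammar- and substitution-rule codec for nucleotide sequence files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grammar- and substitution-rule codec for nucleotide sequence files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassr)
```

## The model

`grassr` compresses raw, FASTA and multi-FASTA nucleotide files losslessly
and without a reference genome. Its premise is statistical, not
repeat-based: a nucleotide file is dominated by five symbols (A, C, G,
T or U, N), while everything else — identifiers, lowercase soft-masking,
the ten other IUPAC ambiguity letters, line wrapping — is sparse,
low-entropy side information that should not dilute the core stream.

**Phase 1** separates those concerns. Per record we keep the identifier
verbatim, fold case and record lowercase runs as `(gap, length)` tuples
(first gap absolute, later gaps measured from the *end* of the previous
run), remove every letter outside the record's core alphabet and record it
as a `(gap, letter-index)` tuple, and keep the layout as a line-length RLE
plus per-record block-length deltas. All positions are 0-based over the
full pre-removal residue coordinates. With `n_seq` residues and `n_spl`
specials, the core stream keeps `n_tar = n_seq − n_spl` characters — an
identity asserted throughout the test suite.

**Phase 2** reduces the alphabet. Counting the five core symbols and
sorting ascending, the three rarest (counts `l ≤ s_l ≤ t_l`) are rewritten
via a flag symbol Z — rarest → `ZZ`, next → `Z`+HFS, third → `Z`+second
HFS — leaving a three-symbol stream of length `ñ = 2(l+s_l+t_l) + o_l`,
where `o_l` is the combined count of the two survivors. The codeword set
`{HFS, sHFS, ZZ, Z·HFS, Z·sHFS}` is prefix-free, hence uniquely decodable;
the suite additionally proves this by exhaustive parse-counting over every
3-symbol string up to length 12. After relabelling (HFS→0, sHFS→1, Z→2),
adjacent digits pair through the fixed nine-symbol table (00→P ... 22→Y),
halving the stream; `floor(ñ/2)` pair symbols plus at most one trailing
digit. Both payloads then pass through a parameter-free general-purpose
backend.

## Design choices where the design was open

* **Tie-breaking.** Symbol ranking must be deterministic even for
  degenerate streams (empty, single-letter). Ties sort by the fixed order
  A < C < G < T/U < N with the later symbol deemed rarer. The ranking is
  stored in the archive header (5 bytes) rather than re-derived by the
  decoder — cheap insurance against any ambiguity.
* **U/T.** A record containing U and no T is flagged RNA; its U occupies
  the T slot through phase 2 and is restored on decode. A record mixing T
  and U treats U as a special character. This keeps a single five-symbol
  model lossless for both alphabets.
* **Static entropy coding.** Lowercase run lengths and special letter
  codes use canonical Huffman with an explicit code-length table. It is
  deterministic and parameter-free, and residual redundancy is picked up
  by the backend anyway. Each section gets its own model; sharing one
  model across sections would couple unrelated value distributions for no
  measurable gain at these stream sizes.
* **Integer serialization.** Positions and lengths are unbounded, so all
  integers are LEB128 varints; signed block-length deltas are zig-zag
  mapped first.
* **Backend.** The final stage is a pluggable contract
  (`bytes → bytes`, lossless, no tuning knobs): bzip2 — a block-sorting
  (BWT-family) compressor — by default, gzip as a dictionary-based
  alternate. Absolute compressed sizes therefore depend on the backend
  chosen; the reproducible surface of this package is the transform
  pipeline and byte-exact losslessness, not any specific benchmark size.
* **Two payloads, not one.** Auxiliary and pair-symbol payloads are
  compressed independently. Cleaner failure isolation and
  section-by-section testability outweigh the slight loss of cross-stream
  context.
* **Fail-loud corruption handling.** The header stores an Adler-32
  checksum of the original input, verified after full reconstruction;
  truncation, bit flips and version skew each raise a typed error.
  Sequence compressors have a history of silently returning same-size,
  wrong-content files; a checksum makes that failure mode impossible to
  miss.
* **Odd-length digit streams** carry their final digit in the header
  instead of padding, so `ñ` is recovered exactly and no sentinel value
  can collide with data.

## Degenerate inputs and numerical corners

Empty files are rejected explicitly (there is no format to detect).
Zero-count symbols still receive a rank, so single-symbol and two-symbol
cores flow through the same code path; an empty core produces an empty
pair stream and a header-only archive body. Decoding validates everything
it consumes: run tuples must reconstruct strictly increasing,
non-overlapping runs, decoded block lengths must be positive and must sum
to the core length plus the special count, and a dangling flag symbol at
the end of the expanded stream is a hard error.

## What the synthetic generator emulates — and what it does not

`generate_input()` produces seeded raw/FASTA/multi-FASTA files with
controllable record counts, length ranges, base composition, IUPAC
ambiguity rate, lowercase-run rate and geometric run lengths, wrap width,
and DNA/RNA alphabet. Defaults (uniform base composition, no specials, no
masking, width 60) model a clean low-repetition archive file, the regime
this codec targets; rates up to 0.3–0.4 in the tests exercise
special-heavy and masking-heavy extremes. The generator draws bases
i.i.d.: it deliberately does not emulate long repeats, palindromes, GC
skew or chromosome-scale structure, and the pipeline exploits none of
those. Passing tests therefore demonstrate correctness (byte-exact round
trips under every layout and alphabet) and formula-level behaviour, not
the compression ratios achievable on highly repetitive real genomes.

## Problem sizes in the shipped suite

The test suite runs round trips over ~250 generated files (records up to a
few hundred bases, all format × alphabet × rate × wrap-width
combinations), per-stage inverse identities on 10,000 random core streams,
exhaustive unique-decodability checks to string length 12, and
backend round trips on 1 MB blobs — sizes chosen so the full suite
finishes in a few minutes while covering every code path; the codec itself
is linear-time and has been exercised on multi-megabyte inputs.

## Known limitations

Only `A–Z`/`a–z` residue letters are supported; digits, gaps (`-`, `.`)
and FASTQ quality lines are out of scope. Line endings must be uniformly
LF or CRLF within a file, and empty lines inside records are rejected.
Archives provide no random access — decompression is whole-file. The
frequency model is global across records, so a multi-FASTA mixing wildly
different compositions is encoded under one ranking.
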