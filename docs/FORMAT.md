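# `.grass` archive format, version 1

All multi-byte integers are unsigned LEB128 varints (base-128, least
significant group first, high bit = continuation) unless stated otherwise.
Signed values are zig-zag mapped (0, -1, 1, -2, ... -> 0, 1, 2, 3, ...)
before varint encoding.

## Header (fixed part)

| bytes | field |
|---|---|
| 4 | magic `"GrSS"` |
| 1 | version (currently 1) |
| 1 | backend id: 0 = bzip2 (BWT-family, default), 1 = gzip (dictionary) |
| 1 | format tag: 0 = raw, 1 = fasta, 2 = multifasta |
| 5 | symbol ranking, ASCII, in order least, second-least, third-least, HFS, second-HFS |
| 1 | trailing digit: 0, 1, 2, or 255 = none |
| 1 | EOL flag: 0 = LF, 1 = CRLF |
| 1 | final-newline flag: 0/1 |
| 4 | Adler-32 of the original input, little-endian |

Magic and version are validated before any payload is touched.

## Payloads

| field |
|---|
| varint: compressed length of auxiliary payload, then that many bytes |
| varint: compressed length of pair-symbol payload, then that many bytes |

Both payloads are compressed independently with the backend named in the
header. The pair-symbol payload decompresses to the ASCII pair stream over
`P,Q,R,S,U,V,W,X,Y`.

## Auxiliary payload (decompressed)

A varint record count, then six sections in fixed order, each wrapped as
`varint length` + body; decoding must consume each section exactly.

1. **identifiers** — varint count (0 for raw format), then per identifier
   varint byte length + verbatim bytes (including the leading `>`).
2. **lowercase runs** — per-record tuple counts (one varint per record),
   then all gaps as varints, then all run lengths as one static-entropy
   stream. First tuple of a record stores the absolute 0-based start;
   later gaps count from the END of the previous run.
3. **special characters** — per-record tuple counts, then all gaps as
   varints, then all letter codes ('A' = 0 ... 'Z' = 25) as one
   static-entropy stream. First gap absolute, later gaps differenced from
   the previous special position.
4. **line-length RLE** — per-record pair counts, then all values, then all
   repeat counts, as varints. Pairs cover maximal runs.
5. **block lengths** — one zig-zag varint delta per record (first absolute).
6. **flags** — per-record RNA bits, packed 8 per byte, LSB first.

## Static entropy stream

Canonical Huffman with an explicit table: varint total value count; if
nonzero, varint distinct-symbol count, the sorted distinct values
(delta-coded varints), one code length per symbol (varints), and — when
there is more than one distinct symbol — varint bit count followed by the
packed code bits (bit order as R's `packBits` on logicals). Canonical codes
are assigned in (length, value) order. A single-symbol stream stores no
bits at all.
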