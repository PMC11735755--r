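Package: grassr
Title: Lossless Reference-Free Compression of DNA and RNA Sequence Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lossless, reference-free compressor for nucleotide sequence
    files in raw, FASTA and multi-FASTA formats. A pretreatment phase
    separates auxiliary information (identifiers, lowercase masking runs,
    IUPAC ambiguity characters, line and block layout) from the core
    A/C/G/T-or-U/N stream; an encoding phase applies a frequency-driven
    grammar rule, a digit substitution and a pairing rule that halves the
    stream, before a parameter-free general-purpose backend compresses the
    payloads. Decompression is byte-exact. Includes compression-ratio
    metrics (CR, WACR, CRIP), a synthetic sequence-file generator for
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
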