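Package: motifkit
Title: Motif Discovery, Scanning, Comparison and Positional Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for sequence-motif analysis in DNA, RNA and
    protein sequences. Provides de novo motif discovery by expectation-
    maximization under OOPS/ZOOPS/ANR site models and by discriminative IUPAC
    word enumeration against dinucleotide-shuffled controls; motif scanning
    with exact position-weight-matrix p-values computed by dynamic programming
    and Benjamini-Hochberg q-values; sequence-level multi-motif scoring with
    combined p-values and block diagrams; motif-motif comparison by optimal
    ungapped alignment with permutation significance; binomial tests of
    central positional enrichment in equal-length sequence sets; reading and
    writing of FASTA and the minimal MEME motif exchange format including
    typed-motif auto-detection; and a planted-motif synthetic sequence
    generator for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
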