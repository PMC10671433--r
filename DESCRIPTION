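Package: homeoshock
Title: Homoeolog Expression Bias and Expression-Level Dominance in
    Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcriptome shock in interspecific hybrids and
    allopolyploids from replicate expression matrices of the hybrid and its
    two progenitors. Pairs homoeologs across subgenomes by reciprocal best
    BLAST hits, classifies homoeolog expression bias (HEB) within the hybrid
    against the parental state, assigns each homoeolog pair to the
    additivity / expression-level dominance (ELD) / transgressive taxonomy
    from a battery of Student t-tests, links ELD calls to per-homoeolog
    up/down/unchanged changes, calls differential expression with fold-change
    and FDR thresholds, and tests gene sets for term over-representation with
    the hypergeometric distribution. Includes a seeded synthetic-data
    generator that emulates replicate FPKM matrices for the three species
    with known per-pair truth states, so the full pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
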