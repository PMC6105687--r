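Package: smmevo
Title: Clonal Dynamics and Mutational Processes in Paired Smoldering and
    Symptomatic Myeloma Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing paired-timepoint whole-genome somatic variant
    data from smoldering multiple myeloma progressing to symptomatic disease:
    trinucleotide-context classification and de novo mutational-signature
    extraction by nonnegative matrix factorization with bootstrap model
    selection, signature catalog matching and nonnegative least-squares
    exposure refitting, two-timepoint subclonal reconstruction with a
    truncated Dirichlet-process mixture over cancer cell fractions,
    static-versus-spontaneous progression classification, kataegis detection
    with breakpoint-proximity permutation testing, rearrangement clonality
    dynamics, and a seeded synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
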