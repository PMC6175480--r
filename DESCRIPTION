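Package: uorfann
Title: Upstream ORF Annotation of 5' UTR Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates single-nucleotide variants in transcript leader (5' UTR)
    sequences for their predicted translational consequence. Detects variant-created
    upstream AUG codons, delineates the resulting upstream open reading frames
    (terminating uORFs, in-frame N-terminal extensions, or out-of-frame overlapping
    ORFs), scores translation-initiation context against the Kozak consensus with a
    transparent position-weight scheme, and classifies each variant or cis-variant
    set with a repression-risk flag. Includes a constraint-driven synthetic
    transcript generator so the full pipeline is testable without any sequence
    download, HGVS c. and strand-aware genomic coordinate handling, and tabular
    (TSV/JSON) reporting designed for diff-stable pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
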