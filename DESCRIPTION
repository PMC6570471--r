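Package: somaticsieve
Title: Somatic Variant Screening for Matched Tumor-Normal Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening somatic variants in matched tumor-normal
    deep amplicon sequencing. Provides a seeded simulator of overlapping PCR
    amplicons with planted germline and somatic variants and an elevated
    read-end error model, a pileup-based low-stringency candidate caller,
    a quality-control cascade (matched-normal subtraction, read-end
    positional exclusion with allele-frequency re-evaluation, multi-allele
    and depth gating, AF-tiered minimum support), codon-level protein-effect
    annotation against a transcript model, and summary statistics
    (glutamate-to-lysine missense enrichment, two-sided Fisher's exact test,
    delta-delta-Ct relative expression). All steps operate on tibbles and
    standard text formats (FASTA, SAM, VCF 4.2, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
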