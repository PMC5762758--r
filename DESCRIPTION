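Package: somakit
Title: Somatic Genome Characterization for Sarcoma-Type Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of integrative
    somatic-genome studies of soft-tissue tumors: supervised mutational-
    signature decomposition by two-pass non-negative least squares with
    signature-specific exposure cutoffs and profile-likelihood confidence
    intervals, chromothripsis calling from segmented copy-number profiles
    via a switch-density criterion, classification of alternative
    lengthening of telomeres (ALT) from C-circle assay intensities and
    telomere qPCR T/S ratios, integration of per-gene lesions with
    allele-specific copy number into genotype classes with biallelic-
    inactivation and whole-genome-duplication calls, and heuristic
    tumor/normal filtering of candidate SNV and indel calls. A synthetic-
    data module generates cohorts with the statistical structure each
    stage assumes, so the whole pipeline is testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    IRanges,
    jsonlite,
    knitr,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
VignetteBuilder: knitr
Config/testthat/edition: 3
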