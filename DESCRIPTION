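Package: clonecord
Title: Clonal Concordance Analysis of Matched Primary-Metastasis Tumor Trios
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of matched normal / primary tumor /
    liver metastasis trios sequenced at high depth on targeted gene panels.
    Implements multi-caller somatic SNV integration with explicit site and
    somatic filter rules, shared-versus-private variant classification with
    per-patient and cohort concordance statistics, 96-channel trinucleotide
    mutation spectra, B-allele-frequency allelic-imbalance segmentation, and
    gene-panel copy-number concordance. A synthetic clonal-evolution cohort
    generator (truncal clone plus low-CCF private subclones, purity-scaled
    allele frequencies, signature-skewed spectra, emulated callers of
    differing sensitivity) makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
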