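Package: heaa
Title: Epigenetic Age Estimation for Humpback Whales from Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for DNA-methylation-based age
    estimation of humpback whales (Megaptera novaeangliae) from targeted
    bisulfite amplicon sequencing. Simulates paired-end bisulfite reads of
    three age-associated promoter amplicons (GRIA2, CDKN2A, TET2) with known
    per-CpG methylation, implements native adapter trimming, quality
    filtering and quality-aware overlap merging of read pairs, performs
    C-to-T-tolerant ungapped alignment and per-CpG methylation-frequency
    calling, applies the three-site Humpback Epigenetic Age Assay (HEAA)
    linear clock with its fixed-width 95 percent confidence interval, and
    builds individual-level cohort summaries and 5-year age structures,
    including replicate-biopsy concordance. Ships the published Hachijojima
    cohort methylation table as an example dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
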