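Package: pepdiff
Title: Differential Analysis of Plasma Peptidome Spectral Counts and
    Precursor Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for label-free differential analysis of endogenous plasma
    peptides observed by LC-ESI-MS/MS. Reads or simulates redundant
    peptide-spectrum-match (PSM) tables, applies the acceptance rules used for
    ion-trap plasma peptidomics (precursor intensity above 1e4 counts, one best
    fit per spectrum, fully tryptic context, tryptic versus phospho-tryptic
    pools), aggregates observation frequencies per gene symbol and treatment,
    corrects counts by treatment totals and tests them with a
    pseudocount-protected chi-square statistic with Benjamini-Hochberg
    q-values, combines peptide-level p-values into cumulative protein
    p-values, and independently compares log10 precursor intensities per gene
    symbol by sequential two-way ANOVA followed by Tukey-Kramer HSD with a
    compact letter display. A seeded synthetic-cohort generator with a known
    truth log supports end-to-end validation of the whole pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
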