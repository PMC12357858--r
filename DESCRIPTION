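Package: oncorank
Title: Integrated Rank Aggregation for Candidate Driver Protein Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate driver proteins across multiple
    mass-spectrometry proteomic datasets by combining length-normalized
    relative abundance, tumor-versus-normal differential statistics, and
    best-cutoff survival association (Kaplan-Meier, Cox-Mantel log-rank,
    Cox hazard ratio) into a single weighted rank-aggregation score
    (Rscore; smaller is better). Includes readers for quantification
    matrices, GMT gene sets and survival cohort tables, a synthetic
    multi-dataset study generator with planted driver proteins for
    end-to-end validation, a full pipeline driver, and ggplot2
    visualizations with broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
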