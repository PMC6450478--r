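Package: medminer
Title: Pattern Mining of Inpatient Medication Administration Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines medication-use patterns from deidentified inpatient
    medication administration records. Cleans raw administration tables
    (route merging, diluent removal), builds per-episode transaction,
    sequence and utility-sequence databases, and mines them with
    from-scratch implementations of FP-Growth (frequent itemsets),
    PrefixSpan (sequential patterns via projected databases) and USpan
    (high-utility sequential patterns). Includes top-k cross-algorithm
    reporting by age group, route-based treatment-pattern shares,
    medication frequency tables, Fleiss kappa for expert rating tables,
    and a synthetic electronic-medical-record generator with planted
    ground-truth patterns for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
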