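Package: microsig
Title: Tissue-Specific Microbial Signature Detection in Low-Biomass
    Taxonomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects tissue-specific microbial signatures in sparse,
    low-depth taxonomic count profiles such as those recovered from host
    RNA-seq. Implements prevalence-based core-microbiome construction,
    cumulative sum scaling (CSS) normalization fit separately per data
    split, iterated one-vs-rest gradient-boosted classification with
    minority up-sampling and a relative-AUPR performance criterion, an
    in-silico contamination resilience test with batch- and site-linked
    pseudo-contaminants, and shuffled-label null models for cross-dataset
    transfer validation. A synthetic-cohort generator with planted
    signatures and batch structure makes the whole pipeline testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
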