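Package: ancestrycat
Title: Standardized Ancestry Categories for Genomics Study Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing the ancestry of genomics study samples in
    two standardized forms: a free-text detailed description and an ancestry
    category drawn from a controlled vocabulary of 17 regional population
    groupings anchored to 1000 Genomes and HapMap reference populations.
    Provides a deterministic cascade that classifies population descriptors,
    reference-population codes and recruitment countries into categories with
    a provenance tier; readers and writers for GWAS-Catalog-style ancestry and
    association tables; an OBO export of the category hierarchy; a metadata
    linter implementing reporting recommendations for authors; diversity
    summaries of individuals, studies and associations by category and time
    window; and a synthetic catalog generator with exact ground truth for
    validating the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
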