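Package: pdoresponse
Title: Chemotherapy Response Classification for Gastric Cancer Organoid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies patient-derived organoid (PDO) drug-screen viability
    profiles into chemotherapy response groups (double-sensitive,
    single-sensitive, not-sensitive) by hierarchical bi-clustering of
    control-normalized viabilities over mechanism-of-action treatment classes;
    derives per-group marker-gene panels from untreated-organoid expression;
    transfers the group labels to external expression cohorts with an explicit
    undefined class; imputes log-IC50 drug response from expression by
    quantile homogenization and cross-validated ridge regression; and
    associates the groups with survival (Kaplan-Meier / log-rank) and somatic
    mutation enrichment (Fisher exact tests). A synthetic-data generator
    emulates every pipeline input with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
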