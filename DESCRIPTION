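Package: epivax
Title: Epitope Selection and Population Coverage for Peptide Vaccine Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for prioritising neoantigen epitopes from
    missense mutations. Given a protein sequence and a mutation list, it
    enumerates mutant peptide windows with matched wild-type windows, expands
    them against HLA allele panels into epitope-allele (EHLA) pairs, computes
    locally evaluable physicochemical descriptors (Kyte-Doolittle
    hydropathicity, GRAVY, instability index, aliphatic index, isoelectric
    point, N-end-rule half-life) and auto-cross-covariance antigenicity
    features, binds externally predicted features (binding rank, stability,
    toxicity, allergenicity, interferon-gamma induction) through a pluggable
    predictor registry with deterministic mocks, classifies and ranks class-I
    pairs with cross-validated random-forest and regression models, applies
    configurable exclusion filters with a per-rule audit, and evaluates
    projected population coverage (coverage, average hit, PC90) under a
    Hardy-Weinberg diploid genotype model, including a minimal set-cover
    optimiser for the smallest pair set preserving coverage. Seeded synthetic
    generators make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
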