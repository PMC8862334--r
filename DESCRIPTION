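Package: specdelim
Title: Supervised Machine-Learning Species Delimitation from Multilocus Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species delimitation for low-dispersal taxa with high population
    structure, where multispecies-coalescent methods tend to over-split.
    Computes population-pair summary statistics (private positions, binned
    folded site-frequency spectrum, within/between pairwise-difference ratio,
    Hudson's FST, longest shared identical tract) from per-locus multiple
    sequence alignments, trains a probability-calibrated support-vector
    classifier from either coalescent-simulated two-population data
    ("general") or a reference taxon with robustly known species limits
    ("custom"), classifies population pairs of a focal complex as conspecific
    or heterospecific, aggregates pairwise calls into a species partition by
    maximizing total log-probability, and evaluates results with a
    same-locality consistency metric. Includes a structured-coalescent
    simulator for isolation-with-migration pairs and hierarchical
    multi-species reference datasets, plus Kimura two-parameter distance
    summaries for judging training-taxon suitability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    e1071,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
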