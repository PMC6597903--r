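Package: dualomics
Title: Integrated Transcriptomic and Proteomic Differential Analysis
    with Ensemble Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis and integration of paired bulk RNA-seq
    and TMT-10plex proteomics from two-genotype, two-timepoint designs,
    as used for iPSC-derived neuronal cultures. Provides median-of-ratios
    size factors and a two-group negative-binomial Wald test for the RNA
    layer; channel-median normalization, relative-ratio transformation and
    an empirical-Bayes moderated t-test for the TMT protein layer;
    correction of isobaric-labelling ratio compression; a
    significance-priority cascade that merges the four differential tables
    into one gene-level integrated signature; and an ensemble gene-set
    enrichment combining over-representation, rank-sum and permutation
    statistics. A seeded synthetic-data generator with known planted
    effects makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
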