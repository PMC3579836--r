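Package: kinfaces
Title: Pedigree, Parentage and Forced-Choice Analysis for Visual
    Kin-Recognition Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for kin-recognition experiments in pedigreed
    primate populations: microsatellite (STR) genotype diagnostics (allele
    frequencies, observed and expected heterozygosity, polymorphic information
    content, Monte-Carlo exact Hardy-Weinberg tests), parentage assignment by
    multilocus exclusion plus likelihood (LOD) confirmation with simulated
    confidence thresholds, recursive pedigree kinship with gene-dropping
    validation and expected relatedness under unresolved paternity,
    constraint-checked kin-discrimination and individual-discrimination triad
    design with restricted-randomized sessions, and mixed-model analysis of
    8-point forced-choice similarity scores with crossed random effects.
    Includes a synthetic-data generator emulating a polygynous multi-generation
    colony, its STR genotype database, and human raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
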