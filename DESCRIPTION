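Package: typhaniche
Title: Hybrid-Zone Classification, Clonal Structure, and Niche Segregation
    Tests for Cattail (Typha) Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing sympatric stands of Typha latifolia,
    T. angustifolia, and their hybrid T. x glauca from codominant
    microsatellite (SSR) genotypes and shoot elevations.  Classifies ramets
    as pure parents, F1 hybrids, or later-generation hybrids from private
    diagnostic alleles and corroborates the calls with a principal
    coordinates ordination of Smouse-Peakall genotypic distances; partitions
    ramets into genets (clones) with a genotyping-error-tolerant one-allele
    mismatch rule; computes genotypic richness R = (G-1)/(n-1); and tests
    for elevation-based niche segregation with a linear mixed model (site
    and genet random effects), a binomial GLMM on genet fractions, and
    two-sample Kolmogorov-Smirnov comparisons.  Includes a synthetic
    hybrid-zone generator with known truth labels for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
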