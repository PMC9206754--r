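Package: microtraj
Title: Age Trajectories in Longitudinal Gut Microbiome Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of age trajectories in longitudinal gut
    microbiome surveys of repeatedly sampled hosts: alpha diversity
    (richness, Faith's phylogenetic diversity, Shannon evenness) and its
    age models, Bray-Curtis and UniFrac dissimilarities, restricted
    permutation Mantel tests of personal signature and temporal stability,
    PERMANOVA with repeated-sampling strata, variable-dispersion beta
    regression of per-taxon relative-abundance trends with core/noncore
    bookkeeping, closest-neighbour personalization models, and dyadic
    grooming (social transmission) analyses. Includes a synthetic cohort
    generator with exported ground truth so every stage is verifiable by
    parameter-recovery and calibration simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    ape,
    vegan,
    picante,
    sandwich,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
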