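Package: paleoturnover
Title: Multiproxy Inference of Prehistoric Population Turnovers
Version: 0.1.0
Authors@R: person("Paleoturnover", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing prehistoric population turnovers from
    ancient-DNA and archaeometric proxies: identity-by-descent (IBD) sharing
    networks with deterministic hierarchical community detection and
    IBD-covariance PCA; supervised ancestry mixture estimation by non-negative
    least squares on relative IBD-sharing rate vectors; ABBA-BABA D-statistics
    with block jackknife; least-squares PCA projection of low-coverage samples;
    a simplified admixture-LD decay dating method; Bayesian radiocarbon
    chronology with a trapezoidal two-phase model and diet-based marine
    reservoir correction from collagen stable isotopes; pigmentation and
    polygenic-score phenotype prediction; and a seeded synthetic-cohort
    generator so the full pipeline is testable without accession data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
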