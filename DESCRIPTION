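Package: forestcensus
Title: Diversity, Composition, Structure and Dynamics of Permanent Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for tree-by-tree permanent forest plot censuses:
    validated census input and census-to-census stem linking, Shannon diversity
    and Pielou evenness, analytic (expected-richness) rarefaction, Bray-Curtis
    dissimilarity with nonmetric multidimensional scaling (Kruskal stress-1,
    isotonic regression, multi-start dimension selection), UPGMA clustering with
    Newick export, Mantel permutation tests, IndVal indicator-species analysis,
    importance value indices, allometric aboveground biomass from diameter,
    modelled height and hierarchically resolved wood density, and annualized
    mortality, recruitment and turnover rates from census intervals. Includes a
    seeded synthetic census generator (habitat-structured log-series
    communities, truncated-Weibull diameters, constant-hazard mortality,
    recruitment influx) so every estimator can be checked against known ground
    truth, and fixtures of published plot summary tables from the southwestern
    Amazon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
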