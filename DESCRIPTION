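Package: resistgen
Title: Landscape Resistance and Allele-Frequency Covariance Models for
    Agricultural Pest Landscape Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for historical landscape genetics of crop-associated
    insects. Harmonizes county-level crop-cover census data across changing
    county boundaries by areal interpolation, computes landscape resistance
    to transmission (LRT) along straight-line transects between sampling
    sites, estimates the relative effect of landscape resistance versus
    geographic distance on SNP allele-frequency differentiation with a
    Bayesian beta-binomial covariance model (Metropolis-within-Gibbs MCMC
    with Gelman-Rubin diagnostics), and provides the supporting
    population-genetic statistics (pairwise Weir-Cockerham FST, nucleotide
    diversity, observed heterozygosity, folded site frequency spectra) and
    regression/Tukey-HSD battery. A synthetic-data module simulates county
    landscapes, census histories and genotypes under the model's generative
    assumptions so the full pipeline can be exercised and tested without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mgcv,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
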