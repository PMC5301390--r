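Package: phylotrace
Title: Post-Processing and Convergence Diagnostics for Phylogenetic MCMC Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing Markov chain Monte Carlo traces from
    Bayesian phylogenetics software (MrBayes, BEAST, PrIMe/JPrIME and similar
    tab-delimited or NEXUS tree-trace formats). Provides burn-in estimation,
    convergence diagnostics (Geweke, Gelman-Rubin, effective-sample-size based),
    parameter summaries with credible intervals and ESS-derived computational
    uncertainty, tree-posterior tabulation with weighted majority-rule consensus
    trees, Robinson-Foulds tree-space analysis with classical multidimensional
    scaling, two-chain comparison tests (Mann-Whitney U, split-frequency
    chi-square), synthetic trace generators for testing, and a JSON-emitting
    command-line front end for scripted large-scale analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    coda,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
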