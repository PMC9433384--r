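Package: riboGrowthLaw
Title: Growth Law Curves from Heterogeneous Translation Speeds and Protein Degradation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A steady-state model of microbial proteome synthesis in which each
    protein has its own translation elongation speed and degradation rate.
    Provides a self-consistent solver for the growth rate and proteome mass
    fractions given a ribosome allocation strategy, environment-correlation
    indices between allocations and speeds (and between mass fractions and
    degradation rates), closed-form growth-law curves relating the ribosomal
    proteome fraction to the growth rate, ensemble simulation of random and
    index-targeted environments, nonlinear growth-law curve fitting with
    confidence-interval propagation to biological parameters (inactive-ribosome
    fraction, ribosomal and average translation speeds), a subsampling RMSE test
    of growth-law universality, synthetic gene-level data generation emulating
    processed ribosome-profiling and proteomics tables, and readers for gene
    tables, growth-law datasets and OD600 time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
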