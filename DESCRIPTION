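Package: blockLik
Title: Blockwise Site Frequency Spectrum Composite Likelihood Inference of
    Demography and Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Approximate composite-likelihood inference of multi-population
    demographic histories together with a genome-wide recombination rate from
    the distribution of blockwise site frequency spectrum configurations
    (bSFS). Blockwise ancestral recombination graphs are sampled under a
    parameterized demographic model (population splits, size changes,
    exponential growth, continuous migration, admixture pulses) and reduced to
    branch lengths per joint-SFS mutation class; configuration probabilities
    follow as products of Poisson probabilities averaged over sampled graphs.
    Includes bSFS/cbSFS tabulation from VCF plus callable-site masks,
    configuration-space enumeration with k-max lumping, a two-stage
    derivative-free search for the maximum composite likelihood estimate,
    blockwise simulation with physical linkage, and a parametric bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
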