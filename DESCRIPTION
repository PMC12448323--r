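Package: recoal
Title: Coalescent Simulation with Recombination and the Bias It Induces in
    Gene-Tree and Theta Estimation
Version: 0.1.0
Authors@R:
    person("recoal", "maintainers", email = "recoal@example.org",
           role = c("aut", "cre"))
Description: Simulates the single-population coalescent with recombination
    (the ancestral recombination graph, ARG) and extracts site-specific
    marginal gene trees.  For three sampled sequences it provides exact
    Jukes-Cantor (JC69) site-pattern probabilities on the two clock trees
    produced by a single recombination event, multinomial likelihoods for
    the five informative site patterns, maximum-likelihood estimation of
    the two coalescence times and of the population-scaled mutation rate
    theta (by numerical marginalization over the coalescent prior), and a
    replicate pipeline quantifying the starlike bias that unmodelled
    intralocus recombination induces in these estimators.  A four-gamete
    test for recombination on biallelic haplotype data is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
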