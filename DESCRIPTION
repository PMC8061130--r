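Package: bymsir
Title: Bayesian Disease Mapping of Small-Area Self-Harm Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-area analysis of self-harm (or other event)
    incidence: reduction of episode-level records to index-episode counts with
    auditable exclusion ledgers, indirect sex/age standardisation of incidence
    ratios (SIRs), Townsend deprivation and Congdon social-fragmentation
    composites with collinearity diagnostics, contiguity adjacency from polygon
    geography, classic and empirical-Bayes population-adjusted Moran's I with
    permutation inference, and a from-scratch Markov chain Monte Carlo sampler
    for the Besag-York-Mollie Poisson model (unstructured plus intrinsic CAR
    random effects) yielding smoothed SIRs, exceedance probabilities, rate
    ratios per standard deviation, DIC and Gelman-Rubin diagnostics. A
    synthetic-data generator with known ground truth supports end-to-end
    validation without access to confidential health records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
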