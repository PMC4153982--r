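Package: genomesizer
Title: Stochastic Dynamics of Genome Size Under Indels, Duplications and
    Large Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the spontaneous evolution of genome size under four
    mutation types (small insertions, small deletions, segmental
    duplications and large deletions) acting as independent Poisson
    processes whose per-generation intensity scales with current genome
    length. Rearrangement sizes may be uniform on the current genome,
    drawn from a lognormal law truncated at the current genome size, or
    taken from an empirical table. Provides mutation-accumulation
    experiments with single-cell bottlenecks, drift analysis of the
    induced multiplicative random walk in log scale, closed-form
    continuous-approximation moments and Cantelli quantile bounds,
    finite-window numerics for the one-mutation and one-generation
    transition kernels including stationary-distribution computation, and
    lognormal fitting of observed rearrangement sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
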