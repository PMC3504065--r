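Package: nkbreed
Title: In Silico Molecular-Breeding Simulations on Modified NK Fitness Landscapes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A testbed for comparing breeding-programme strategies in silico.
    Generates tunably rugged NK fitness landscapes over binary genomes,
    augments them with a trait-weighted, threshold-modified objective that
    models optimising a breeder's trait at the expense of overall viability,
    and runs six evolutionary algorithms against them: three phenotype-only
    strategies (a (1+lambda) breeder, a generational genetic algorithm, and a
    spatially structured local-mating algorithm) and three genotype-aware
    strategies (a niching genetic algorithm with dynamic-radius fitness
    sharing, and two rule-guided algorithms that induce attributional
    locus=allele rules from fitness strata to restrict mating pools). A
    replicated comparison harness with a diversity-preserving burn-in,
    matched starting populations, rank statistics and per-locus Shannon
    entropy supports reproducible head-to-head experiments, driven either
    from R or from a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
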