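Package: suprapop
Title: Cross-Species SNP Sharing, Drift Persistence Times and
    Wright-Fisher Simulation for Hybridising Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing shared single-nucleotide polymorphisms
    among closely related, hybridising species. Provides genotype-matrix
    input/output (tabular and VCF), per-population quality control
    (minor-allele frequency, observed heterozygosity, missingness, exact
    Hardy-Weinberg tests), cross-species polymorphism-sharing summaries,
    the closed-form neutral-drift persistence-time calculus with
    effective-population-size scaling and retention-threshold scenarios,
    a forward-time Wright-Fisher simulator (single population and two
    populations coupled by gametic gene flow) validated against an exact
    Markov-chain oracle, and a synthetic genotype-panel generator
    emulating SNP panels ascertained in a focal species.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
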