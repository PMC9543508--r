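Package: draftscope
Title: Pool-Seq Divergence, Genetic Draft Simulation, and SNP Outlier Tests
    for Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Draftscope", "Developers", email = "draftscope@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled-sequencing data from short-term
    experimental evolution. Reads and filters per-SNP read-count tables,
    computes windowed nucleotide diversity and pairwise FST for pools,
    estimates lineage-specific null variances of angular-transformed
    allele-frequency change by robust scale estimation and generalized
    least squares with a block-bootstrap covariance, simulates
    multi-chromosome diploid genomes under full selfing or random
    outcrossing with one obligate crossover per chromosome and optional
    strong selection at one or two loci, calibrates census size against
    observed null variances, and fits nine competing Gaussian models of
    per-SNP evolution with AIC model selection and Sidak-corrected
    likelihood-ratio outlier tests. A synthetic-data module generates
    complete four-population experiments with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
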