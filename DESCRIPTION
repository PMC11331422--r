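Package: paralogsel
Title: Selection Divergence Analysis for Duplicated Gene Pairs on Phylogenies
Version: 0.1.0
Authors@R:
    person("Paralogsel", "Developers", email = "paralogsel@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether selection on a functional site diverged
    between two gene duplicates. Implements a two-state continuous-time
    Markov model of binary trait evolution on a rooted phylogeny with
    lineage-class-specific loss rates, including maximum-likelihood fitting,
    nested likelihood-ratio tests, Metropolis-Hastings MCMC with exponential
    rate priors, ancestral-node fossilization, stepping-stone marginal
    likelihoods and log Bayes factors; site-level dN/dS estimation and
    between-partition contrasts (FEL and Contrast-FEL style) under an
    MG94xHKY codon model with F3x4 frequencies; extraction of binary residue
    traits from protein alignments relative to a reference sequence
    position; sodium self-inhibition statistics from voltage-clamp current
    traces with group comparisons; RPKM/FPKM expression calls; and
    seed-reproducible simulators for every input class.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
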