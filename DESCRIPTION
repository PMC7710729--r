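Package: sweepfunc
Title: Haplotype-Based Selection Scans with Functional Follow-Up Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage toolkit for detecting and functionally characterizing
    recent positive selection on an ion-channel gene. Implements an extended
    haplotype homozygosity (EHH) / integrated haplotype score (iHS) selection
    scan with 30 kb window aggregation and simulation-derived significance
    thresholds; a forward-in-time Wright-Fisher simulator (multi-population
    demography, recombination, selective sweeps from standing variation) used
    to build the neutral null; population-genetic summaries (allele, genotype
    and two-locus haplotype frequencies, D/D'/r2 linkage disequilibrium,
    Hudson and Weir-Cockerham per-site Fst); quantification of whole-cell
    patch-clamp recordings (capacitance-normalized I-V relations, AUC,
    Gaussian amplitude-histogram single-channel fits, NPo, slope conductance,
    tail-deactivation kinetics) with a stochastic two-state Markov gating
    simulator; and hydrogen-bond distance statistics over conformational
    ensembles of protein models, including an exact/approximate Mann-Whitney
    U test. Synthetic-data generators for every stage make the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    mclust,
    minpack.lm,
    pracma,
    bio3d,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
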