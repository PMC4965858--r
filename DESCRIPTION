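Package: speccount
Title: Label-Free Spectral-Count Differential Proteomics
Version: 0.1.0
Authors@R:
    person("speccount", "maintainers", email = "maintainers@speccount.dev",
           role = c("aut", "cre"))
Description: Differential protein expression analysis from label-free
    spectral counting. Reads protein-level identification reports (spectral
    counts per sample), applies identification acceptance and exclusion
    filters (probability, unique peptides, contaminant/decoy/cDNA-like
    rows), computes depth-normalized signed spectral-count ratios (Rsc) with
    a pseudocount correction, tests per-protein count differences between
    two cohorts with a two-sided Fisher exact test and Benjamini-Hochberg
    adjustment, partitions differential proteins into cohort-unique and
    common enriched/diminished classes, summarizes sample structure
    (correlation matrix, hierarchical clustering with Newick export,
    detection overlap), performs local gene-set over-representation
    analysis against GMT collections, and ships a negative-binomial
    synthetic report generator with planted ground truth for end-to-end
    validation. A command-line entry point orchestrates the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
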