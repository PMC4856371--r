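Package: treeseqsim
Title: Exact Coalescent Simulation and Tree-Sequence Analysis with Sparse
    Trees and Coalescence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the exact coalescent with recombination using
    Hudson's algorithm over sparse oriented trees, recording the output as
    coalescence records.  A tree sequence (a column-indexed table of
    coalescence records) encodes all correlated marginal genealogies along
    a chromosome in O(n + rho*log(n)) space.  The package provides the
    tree-sequence data model and validation, point queries for the
    marginal tree at a site, sequential generation of all marginal trees
    and of the record differences between adjacent trees, leaf-count
    maintenance for allele-frequency and case/control odds-ratio
    calculations, infinite-sites mutation simulation, haplotype
    extraction, serialisation (tab-delimited text, an HDF5 container,
    Newick and ms-style output), a small command-line front end, and
    verification experiments for the analytic properties of the
    simulator (Kingman limit, Hudson-Kaplan breakpoint expectation,
    record-count bound, quadratic event growth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
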