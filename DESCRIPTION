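Package: panelforge
Title: Characterization of Structured Crop Diversity Panels for Association Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end characterization of structured diversity panels of
    inbred crop accessions, as used to prepare rice germplasm collections for
    genome-wide association studies. Provides marker quality control for
    dominant (presence/absence) and biallelic SNP data, dissimilarity indices
    and neighbor-joining trees with core-collection selection by maximum
    length subtree pruning, maximum-likelihood admixture-model population
    structure with Evanno delta-K model choice and membership-threshold
    assignment, discriminant analysis of principal components, pairwise
    Weir-Cockerham-style FST with permutation tests, linkage-disequilibrium
    decay estimation by distance-binned r-squared and power-law fitting,
    nearest-haplotype imputation, kinship estimation and Q+K mixed-model
    association mapping, plus a synthetic panel generator that emulates a
    bipolar indica/japonica population structure with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
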