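Package: segshare
Title: Identity-by-Descent Segment Sharing Statistics for Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of identity-by-descent (IBD) segments in
    population cohorts: reading and filtering Refined-IBD-style segment files
    against HapMap or PLINK genetic maps, population-pair mean sharing
    statistics with relatedness exclusion, nonparametric bootstrap confidence
    intervals over individuals, log-scale sharing heat maps, PCA-space
    nearest-neighbour population networks with Cytoscape export, principal
    component vs. geography correlations, SNP-array merging and QC filters
    (strand-ambiguous markers, per-population missingness, minor allele
    frequency, exact Hardy-Weinberg test, windowed LD pruning), and a
    synthetic-data generator that emulates the statistical structure of IBD
    sharing so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
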