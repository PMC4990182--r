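Package: polyadapt
Title: Detecting Polygenic Adaptation in GWAS-Derived Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for detecting polygenic adaptation in the
    systems genetics of complex traits. Variants from GWAS summary statistics
    are screened for haplotype-based signatures of recent positive selection
    (integrated haplotype score, iHS), combined into gene-level association
    p-values with a Monte-Carlo multivariate-normal null calibrated by
    reference-panel linkage disequilibrium, assembled into dense modules on a
    protein-interaction network, screened for long-distance genotypic LD
    (epistasis) with Storey q-value FDR control, and summarised by
    hypergeometric term enrichment. A synthetic-data generator with planted
    selective sweeps, trait genes, network modules and epistatic pairs allows
    the full pipeline to be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
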