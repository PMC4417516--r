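Package: agingtx
Title: Age-Association, Co-Expression Network Stability and Methylation
    Mediation Analysis for Monocyte Transcriptomes
Version: 0.1.0
Authors@R:
    person("Cohort", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for aging-transcriptomics cohorts:
    covariate-adjusted linear-model scans of age against expression and
    DNA-methylation matrices with Storey q-value FDR, weighted gene
    co-expression network construction (biweight midcorrelation, soft
    thresholding with scale-free fit, topological overlap, hierarchical
    module detection and module eigengenes), a subsampling/Jaccard
    consensus-stability procedure for module assignments, decomposition
    of age effects on expression into methylation-mediated indirect and
    direct paths with bootstrap inference, per-sample cell-contamination
    enrichment scoring, and gene-set overrepresentation testing.
    Includes a synthetic-cohort generator that plants known age effects,
    co-expression blocks, mediating CpGs and cell-type contamination for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
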