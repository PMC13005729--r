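Package: enrichclust
Title: Gene-Overlap Clustering, Pooling and Annotation of Multi-Condition
    Enrichment Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces redundancy in gene-set enrichment results collected
    across several gene-set databases and experimental conditions. Runs an
    offline hypergeometric over-representation test against user-supplied
    GMT libraries, builds a Jaccard similarity graph over the retained
    terms, detects gene-coherent term clusters with the Walktrap community
    algorithm, pools per-term p-values within each cluster (Fisher,
    Stouffer, weighted Z or Cauchy combination), generates plain-text
    prompts for language-model based cluster annotation, and exports
    heatmap and bubble-plot summaries that compare conditions side by
    side. Includes a synthetic benchmark generator with planted cluster
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    patchwork,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
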