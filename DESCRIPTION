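Package: tfprio
Title: Prioritizing Transcription Factors and Cell Wall Genes in Stress
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing transcription factors (TFs)
    and cell-wall-protein (CWP) genes involved in the Arabidopsis thaliana
    leaf response to water deficit. Calls per-experiment differentially
    expressed genes (DEGs) from log2 expression matrices, identifies stably
    unidirectional DEGs across a multi-experiment compendium with a binomial
    vote-counting rule, filters a bipartite TF-to-target regulatory network by
    drought-related process annotations and stable differential expression,
    scores each TF by the number of experiments in which its CWP target set
    is hypergeometrically enriched for DEGs (STF), selects priority TFs,
    reduces the network to them, and ranks CWP genes by their TF in-degree
    (SCWP). Ships a synthetic-data generator with planted drought regulators
    so every stage is testable against known ground truth.
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
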