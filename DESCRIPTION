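Package: chromotif
Title: Chromatin-State-Marked Network Motif Discovery and Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, signed transcription-factor-to-gene regulatory
    networks from promoter, ChIP-seq binding-site and DNase-hypersensitivity
    intervals; assigns 15-class chromatin states to promoters and binding
    sites by fold enrichment; censuses connected three-node subgraphs colored
    by node states and scores their over-representation against a
    degree-preserving edge-swap null; classifies feedforward loops as
    coherent or incoherent by edge sign; and screens state-marked feedforward
    loops as survival biomarkers with an equally weighted expression risk
    score, median split and log-rank test. A synthetic-data module generates
    toy genomes, segmentations, peak sets, expression panels and survival
    cohorts with planted ground truth so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
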