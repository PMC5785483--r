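Package: oralmia
Title: Oral Microbiome Profiling and a Microbial Index for ASD Screening
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-habitat (saliva and supragingival
    plaque) oral 16S OTU count tables from case-control autism spectrum
    disorder (ASD) studies: rarefaction and alpha-diversity indices (ACE,
    Shannon, Shannon evenness, Good's coverage), UniFrac distances with
    PCoA ordination and one-factor PERMANOVA, Wilcoxon rank-sum
    differential-abundance screening with Benjamini-Hochberg FDR control,
    Spearman co-occurrence networks, random-forest marker ranking with
    cross-validated panel-size selection, and a composite "microbial index
    of ASD" (MIA) diagnostic score with exhaustive panel enumeration,
    ROC/AUC evaluation and Youden cut-off selection. Includes a synthetic
    OTU-table generator emulating the two-group, two-habitat study design
    so every stage is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
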