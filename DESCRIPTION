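Package: molproc
Title: Molecular Process Models of Disease and Drug Mechanism of Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives molecular process models of a clinical phenotype and of
    a drug mechanism of action from gene signatures mapped onto a consolidated
    protein-protein interaction network, and computes their interference to
    nominate process segments carrying predictive biomarker candidates.
    Provides readers for edge-list and PSI-MI-TAB-like interaction tables, GMT
    pathway collections and identifier/ortholog mapping tables; multi-study
    signature consolidation and k-of-m consensus signatures; an MCODE-style
    k-core vertex-weighting segmentation of the signature-induced subgraph;
    permutation nulls for inter-segment interaction counts; Fisher's exact
    enrichment with Benjamini-Hochberg correction; drug-disease model
    interference reports; and cardinality-exact synthetic study generators so
    the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
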