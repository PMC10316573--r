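Package: coocnet
Title: Co-Occurrence Network Analysis for Microbiome Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signed co-occurrence network inference from taxon abundance
    tables via tie-aware Spearman correlation with Benjamini-Hochberg
    false-discovery control, topological characterization against
    randomized-graph null ensembles, Louvain module detection with the
    M > 0.4 modularity criterion, within-module degree (Zi) and
    participation coefficient (Pi) node-role classification for keystone
    taxon screening, alpha diversity and Bray-Curtis community metrics,
    Wilcoxon rank-sum differential abundance, and taxon-trait association
    screening. Includes a synthetic community generator with planted
    correlation modules, keystone nodes, and trait-linked taxa for
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
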