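Package: cagpipe
Title: Downstream Metagenomic Analysis with Co-Abundance Gene Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable downstream analysis pipeline for shotgun
    metagenomic gene catalogs, modelled on longitudinal gut-microbiome
    succession studies. Aggregates gene-level abundance profiles to
    taxonomic and functional profiles, computes alpha diversity
    (Shannon, Pielou, Chao1, rarefaction), Whittaker-dissimilarity
    ordination with PERMANOVA, clusters catalog genes into co-abundance
    gene groups (CAGs) by canopy clustering with metagenomic-species
    (MGS) calling, screens biomarkers by Wilcoxon/Holm testing and a
    linear-discriminant effect size, and discovers structurally
    important ("keystone") genera by intersecting hub genera of a
    significance-pruned Spearman correlation network with top
    random-forest Gini importances. Includes a synthetic-data generator
    with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
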