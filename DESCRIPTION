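Package: tuberstab
Title: Microbiome Analysis of Potato Tuber Storage Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bacterial OTUs associated with the storage stability
    of potato tubers from 16S rRNA amplicon count tables. Implements
    reproducible-OTU (rOTU) filtering, rarefaction, alpha diversity with
    permutation ANOVA, Bray-Curtis beta diversity with PERMANOVA and
    (constrained) principal-coordinates ordination, random-forest
    backward-elimination indicator selection, a thresholded Spearman
    co-occurrence network with a storage-time node, and the intersection of
    the two selection routes into direction-labelled key OTUs, together with
    linear-model statistics for in vitro sprouting assays. A
    Dirichlet-multinomial study simulator with planted storage-associated
    taxa supports validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    randomForest,
    MASS,
    emmeans,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
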