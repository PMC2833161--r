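Package: foresite
Title: Unsupervised Discovery of Functional Sites from Protein Structure Microenvironments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase clustering of protein structure microenvironment
    vectors for unsupervised functional-site discovery. Microenvironments
    (radially binned physicochemical property vectors around a site of
    interest) are standardized, reduced by principal components, coarsely
    partitioned by spherical k-means under cosine distance, then refined by
    single-linkage hierarchical clustering. Tree nodes are scored by a
    combination of internal node correlation, literature-based functional
    coherence (the neighbor-divergence-per-gene statistic over a
    protein-to-document corpus), and cluster size; an optimal disjoint set
    of nodes is selected and annotated by hypergeometric term enrichment
    with Bonferroni correction and an entropy-by-idf literature score.
    Includes deterministic synthetic generators for planted vector clusters
    and topic-structured knowledge corpora, evaluation utilities (dilution
    series, silhouette, purity, adjusted Rand index, parameter sweeps),
    and static HTML cluster reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    cluster,
    mclust,
    bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
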