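Package: wmcna
Title: Weighted Correlation Network Analysis for Metabolomic Profiles
Version: 0.1.0
Authors@R: person("Open", "Metabolomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds weighted correlation networks from metabolite abundance
    tables (for example NMR-profiled concentrations), computes topological
    overlap, detects co-abundance modules by hierarchical clustering of the
    topological-overlap dissimilarity, summarises modules by eigenmetabolites
    and associates them with categorical sample traits by ANOVA with
    Bonferroni control and compact letter displays. Also provides the
    fundamental network statistics (connectivity, scaled connectivity,
    maximum adjacency ratio, clustering coefficient, density, centralization,
    heterogeneity), two baseline analyses (PCA with loading screening and a
    batch-learning self-organizing map with heat-map style cell comparisons),
    NMR fingerprint binning, a synthetic-data generator with planted module
    structure and genotype effects, and a command-line pipeline with standard
    export formats (TSV, SIF, GraphML, Newick).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
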