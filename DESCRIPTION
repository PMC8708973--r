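Package: glioquant
Title: Marker-Positive Cell Quantification in Multiplex Immunofluorescence
    and Single-Cell CNV-Based Malignancy Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies DCX-, OLIG2- and NES-positive cells in four-channel
    multiplex immunofluorescence images of glioblastoma tissue using a
    nuclei-seeded Voronoi tessellation with marker-specific positivity rules
    (nuclear overlap for OLIG2, perinuclear adjacency for DCX and NES), and
    annotates single cells as cancer or normal from UMI count matrices via a
    reference-centred, genomically smoothed expression residual scored for
    chromosome-7 gain and chromosome-10 loss. Includes ground-truthed
    synthetic generators for both data modalities, per-spot frequency
    summaries, and the accompanying nonparametric statistical layer
    (Wilcoxon rank-sum and signed-rank, Kruskal-Wallis, Spearman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
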