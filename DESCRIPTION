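Package: surfgradcam
Title: Interpretable Multi-View CNN Grading of Alveolar Bone Defects on
    Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grades the severity (0-3) of alveolar bone defects in cleft lip
    and palate patients from triangle surface meshes of the maxilla. A
    fly-by multi-view pipeline renders each mesh from cameras sampled on a
    surrounding icosphere, encodes every snapshot with a small convolutional
    network, aggregates the views through a gated attention layer, and
    classifies the shape into four severity grades. Each decision is
    explained by surface Grad-CAM: per-view class activation maps are
    max-pooled through exact pixel-to-face correspondences back onto the
    mesh as a vertex heatmap. Includes a parametric generator of labeled
    synthetic cleft-arch meshes, readers and writers for VTK, VTP, OBJ and
    PLY polydata with named per-vertex scalar arrays, a z-buffer rasterizer
    with face-identifier buffers, and a stratified five-fold evaluation
    suite reporting per-class precision, recall, F1, one-vs-rest AUC,
    confusion matrices and within-one-grade agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    ggplot2
Config/testthat/edition: 3
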