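Package: molembed
Title: Multimodal Molecular Embeddings from 2D/3D Structure and Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for joint molecule-text representation
    learning. Molecules are encoded by a graph Transformer whose attention is
    biased by combined 2D (shortest-path and bond-feature) and 3D
    (Gaussian-basis-kernel interatomic distance) pairwise structural encodings;
    free text is encoded by a standard Transformer encoder. The two encoders
    are trained jointly under cross-modal and self contrastive losses over
    RMSD-gated molecular augmentations (node dropping, random-walk subgraph
    sampling, functional-group transformation, BRICS substructure removal).
    Downstream harnesses cover cross-modality retrieval, property prediction,
    and text-prompted molecule editing through an invertible generator latent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
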