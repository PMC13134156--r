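Package: molgps
Title: Local and Global Attention Architectures for Atomistic Graph Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A unified framework for studying when global attention helps in
    molecular property prediction. Provides four switchable model classes on
    atomistic graphs -- plain message passing networks (MPNN), MPNNs augmented
    with chemical/topological/spectral encoders, GPS-style hybrids of message
    passing with multi-head global attention, and fully fused local/global
    models -- together with radius-cutoff graph construction, Laplacian
    positional encodings, fusion embeddings, multitask training with early
    stopping and checkpointing, conditional random hyperparameter search, and
    a synthetic molecular-graph generator exposing short-range and long-range
    (dispersion-like) targets so the local-versus-global question is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
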