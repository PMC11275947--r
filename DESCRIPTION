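Package: genet
Title: Gene Expression Prediction from Transcription Factor Binding and
    H3K27ac Using Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene expression from two epigenomic views --
    transcription-factor binding and H3K27ac histone acetylation -- measured
    as binned ChIP-seq peak signal in a window around each transcription
    start site. Samples (gene, cell line pairs) are connected in weighted
    cosine-similarity networks, one graph convolutional network per view is
    trained to emit soft expression-class predictions, the two views are
    fused through a cross-feature discovery tensor (the outer product of the
    per-view soft labels), and a small regression head maps the flattened
    tensor to expression. Includes readers for narrowPeak/BED6/GTF/TSV
    inputs, the five standard regression baselines, train/validation/test
    protocol utilities (70/15/15 splits, metrics, learning-rate x
    hidden-size grid search, TSS-window sweep), and a synthetic ENCODE-like
    data generator with a planted regulatory signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
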