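Package: elastica
Title: Elastic Embedding for Large Single-Cell Expression Matrices
Version: 0.1.0
Authors@R:
    person("Elastica", "Developers", email = "elastica@example.org",
           role = c("aut", "cre"))
Description: Nonlinear dimensionality reduction of bulk and single-cell
    expression matrices by elastic embedding (EE) and its time-series
    extension (TSEE). Attractive weights are calibrated per sample to a
    target perplexity by entropic-affinity root finding; the embedding is
    optimized with a spectral-direction quasi-Newton scheme that factorizes
    the regularized attractive graph Laplacian once and reuses it every
    iteration. A row-partitioned execution mode reproduces the serial
    result with per-worker block storage and rank-ordered reductions.
    Includes a minimal count-matrix preprocessing pipeline (filtering,
    log-normalization, variable-gene selection, PCA), synthetic generators
    for branching, clustered, and staged time-series data, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
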