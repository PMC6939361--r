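Package: vsbind
Title: Vector-Symbolic Sequence Binding with Holographic Reduced
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling structured sequence processing with a
    vector-symbolic architecture based on Plate's holographic reduced
    representations (HRRs). Provides the core HRR algebra (superposition,
    circular-convolution binding, involution, unbinding, cosine comparison
    and cleanup against a vocabulary), deterministic boundary-relative
    positional tags built as convolutional powers of unitary base vectors,
    a decaying serial-order working-memory buffer with primacy and recency
    weighting, salience-filtered encoding of adjacent and non-adjacent
    dependencies, recursive hierarchical (nested and crossed) chunk
    encoding with key-based retrieval, oscillator-gated scheduling of
    binding operations with phase-based position coding, and synthetic
    artificial-grammar generators with Monte-Carlo capacity benchmarks and
    activation and orthogonality reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
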