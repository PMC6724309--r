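Package: netamp
Title: Network Perturbation Amplitude Scoring for Two-Layer Causal Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how strongly a treatment perturbs a causal biological
    network from transcriptomic contrasts. A two-layer network couples a
    signed functional backbone (protein activities, transcription factors)
    to a transcript layer of downstream genes. Gene log2 fold-changes are
    propagated backwards onto the backbone by constrained least-squares
    smoothing with the signed graph Laplacian, and the Network Perturbation
    Amplitude (NPA) is scored as an edge-averaged quadratic form. Each score
    is accompanied by a delta-method confidence interval and two permutation
    statistics (transcript-layer and backbone reshuffling), decomposed into
    leading nodes, and aggregated across network families into a relative
    Biological Impact Factor (BIF) with a similarity index. Includes a
    synthetic-data generator for two-layer networks and contrasts with
    planted coherent perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
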