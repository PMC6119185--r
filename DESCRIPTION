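Package: senescnet
Title: Dynamic Modeling of Transcriptional Regulatory Networks from
    Time-Course Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A network-science pipeline for time-course gene expression,
    motivated by the onset of leaf senescence. Detects per-time-point
    differential and "emergent" genes, builds weighted co-expression
    networks (soft thresholding, topological overlap, module detection,
    eigengenes), analyses network topology (hubs, clustering coefficients,
    shortest paths, information centrality, hypergeometric regulator
    enrichment), overlays transcription-factor and microRNA regulation
    into a signed directed network, mines dynamic bifurcation paths from
    time series, simulates the regulatory logic as a hybrid
    Boolean/continuous dynamical system with clamping perturbations, and
    quantifies qPCR amplification kinetics by the Cy0 tangent method. A
    fully specified synthetic-data generator with planted ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    MASS,
    deSolve,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
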