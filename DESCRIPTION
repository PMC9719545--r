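Package: dualcomm
Title: Primal and Dual Communities in Plane Flow Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spatially embedded flow networks through graph
    duality. Constructs weighted dual graphs of plane networks (faces as nodes,
    inverse-weight edges), detects primal and dual communities and hierarchies by
    spectral bisection of the corresponding graph Laplacians, and bounds their
    algebraic connectivity by cut-set and cut-path weights. Quantifies how both
    community types suppress failure spreading in linear flow networks (edge
    sensitivity factors in primal and dual form, line-outage flow changes, mean
    flow ratios), in weighted threshold cascades, and in second-order phase
    oscillator networks. Includes an optimal supply-network simulator in which
    fluctuating sources drive a transition from primal to dual community
    structure, plus deterministic synthetic lattice generators and plain-text
    graph input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
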