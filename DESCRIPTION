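Package: fsfn
Title: Hierarchical Fractal Scale-Free Networks by Edge Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction and exact analysis of hierarchical fractal
    scale-free networks (FSFNs) grown by iterated edge replacement with a
    small rooted graph (a generator). Provides deterministic and stochastic
    builders, closed-form structural theory (degree-count tables, moments,
    power-law and fractal exponents, average and global clustering, joint
    degree distributions, assortativity and Spearman rank correlation), a
    renormalization theory of the bond-percolation transition (two-terminal
    reliability polynomial, critical point, correlation-length and
    order-parameter exponents via a 2x2 transfer matrix), and Monte-Carlo
    percolation simulation with finite-size scaling collapse. Such networks
    serve as null models for fractal topologies observed in protein
    interaction networks and epidemic substrates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
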