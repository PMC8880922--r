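Package: stripegrn
Title: Design-Space Exploration of Stripe-Forming Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates three-gene regulatory networks on a one-dimensional
    field of cells under a static exponential morphogen gradient, scores how
    well the resulting expression phenotypes match a central stripe, and
    searches the multi-input network design space with a hill-climbing
    Markov-chain sampler. The catalog of stripe-forming designs is analysed
    by signed-digraph isomorphism classification, motif census, neutral
    network (metagraph) construction, Shannon entropy, degree-based
    complexity, parameter and environmental robustness, diffusion
    independence, field-size scaling, and distance-based clustering of
    spatiotemporal phenotypes and subgraph profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
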