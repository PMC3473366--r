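Package: lddr
Title: Multi-Valued Logical Modelling of DNA Damage Response Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Engine for discrete logical models of signal transduction with
    multi-valued (0/1/2) components, sum-of-products logical functions and
    time-scale annotations. Computes logical steady states under clamps,
    signed interaction graphs, dependency matrices, feed-forward and feedback
    loop censuses with functionality contexts, asynchronous state-transition
    graphs under ranked priority classes with attractor detection,
    attractor-preserving model reduction, and minimal intervention sets.
    Ships the six-component DNA damage response core model (p53 / NF-kB) and
    a seeded generator of random logical networks for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
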