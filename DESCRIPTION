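Package: dms2func
Title: Supervised Sequence-Function Models for Deep Mutational Scanning Data
Version: 0.1.0
Authors@R:
    person("dms2func", "maintainers", email = "dms2func@example.org",
           role = c("aut", "cre"))
Description: Tools to learn the protein sequence-function mapping from deep
    mutational scanning (DMS) datasets. Variants are encoded per residue as a
    21-letter one-hot block concatenated with a principal-component projection
    of amino-acid physicochemical properties. Four regression architectures
    are provided (linear, fully connected, sequence convolutional, and an
    order-independent graph convolutional network over a residue contact
    graph), trained with Adam, mean-squared-error loss and early stopping.
    The package also implements random and extrapolation dataset splits,
    ranking metrics (recall at budget, top-N statistics), a library-size
    versus sequencing-read resampling simulator with log-ratio enrichment
    scoring, integrated-gradients attributions, latent-representation
    extraction, full single-mutant prediction matrices, ensemble-guided
    fixed-distance hill-climbing sequence design, and a seeded synthetic
    fitness-landscape generator for fixtures and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
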