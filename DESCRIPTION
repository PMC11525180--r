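Package: hexdmn
Title: Connectome-Constrained Deep Mechanistic Networks on Hexagonal Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains connectome-constrained, task-optimized recurrent
    network models of the fruit fly optic lobe. Cell-type filter tables with
    synapse counts and signs are compiled onto a hexagonal retinotopic lattice
    into a threshold-linear voltage model integrated with the Euler method.
    Free parameters (per-type time constants and resting potentials, per
    type-pair unitary synapse strengths) are optimized by backpropagation
    through time on an optic-flow decoding task. Includes the field's standard
    stimulus protocols (circular flashes, moving edges, single-ommatidium
    flashes) and tuning statistics (flash response index, direction selectivity
    index with permutation nulls, spatio-temporal receptive fields), ensemble
    clustering and ranking, and a sparse-connectome identifiability simulation
    with Dale's-law feedforward networks and lottery-ticket pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    mclust,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
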