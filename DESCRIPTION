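Package: codexpp
Title: Preprocessing of Cyclic Multiplexed Fluorescence Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end preprocessing of cyclic multiplexed immunofluorescence
    (CODEX-style) tile acquisitions. Deconvolves z-stacks with an accelerated
    single-iteration Richardson-Lucy scheme using a Wiener-Butterworth
    unmatched back projector and a Born-Wolf point-spread function, corrects
    axial focus drift by per-tile/per-channel/per-cycle focus-measure plane
    selection, compensates between-cycle lateral drift by Fourier phase
    correlation, stitches tile grids with a mechanical stage model and linear
    blending, subtracts blank-cycle background, detects and zeroes
    high-intensity autofluorescent objects such as erythrocytes, and emits an
    aligned multi-channel multi-cycle hyperstack. Includes a synthetic
    experiment generator with ground-truth manifests so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    MASS,
    jsonlite,
    parallel,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
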