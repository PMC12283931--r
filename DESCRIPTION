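Package: tubeflex
Title: Persistence Length, Morphometry and Thermal Stability of Fluctuating
    Protein Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterisation of semiflexible filaments such as
    designed protein nanotubes and actin. Estimates persistence length from
    thermally driven shape fluctuations via the two-dimensional worm-like-chain
    relation between contour length and mean-square end-to-end distance,
    extracts ordered filament skeletons from fluorescence image stacks and
    links them across frames, measures tube lengths from closed outlines by
    the half-perimeter rule with Welch two-sample comparison, and fits
    thermal denaturation curves with a four-parameter logistic to recover the
    melting midpoint. Includes a synthetic-data module (equilibrium
    worm-like-chain sampler plus a fluorescence renderer with Gaussian PSF and
    Poisson noise) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
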