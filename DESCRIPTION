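Package: adsorbkin
Title: Reaction-Layer Kinetics of Nanoparticle Adsorption on Supported Lipid Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts capacitance-current peak-suppression time series, recorded
    while silica nanoparticles adsorb onto supported DOPC phospholipid
    monolayers, into a size-independent heterogeneous adsorption rate constant.
    Implements the reaction-layer geometric model (per-particle and per-mmol
    reactive areas, hexagonal close-packed coverage, size-specific maximum peak
    depression), initial-rate and normalized-rate extraction by ordinary least
    squares, the bottom-up and top-down rate-constant derivations with
    first-order error propagation, dissolved-silica reactive-area estimates,
    and a seeded synthetic-trace generator for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
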