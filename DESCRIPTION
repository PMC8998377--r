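Package: lersim
Title: Landscape Ecological Risk Assessment and Patch-Generating
    Land-Use Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based landscape ecological risk assessment from
    categorical land-use rasters and multi-scenario projection of future
    land use with a patch-generating cellular automaton.  Computes
    per-class landscape pattern metrics (fragmentation, separation,
    fractal dimension), combines them with landscape vulnerability into a
    landscape ecological risk index (ERI) over square evaluation units,
    interpolates risk surfaces by ordinary kriging and classifies them
    into grades by Jenks natural breaks.  Land-use change is projected by
    learning per-class growth probabilities from observed expansion with
    a random forest (land expansion analysis strategy) and allocating
    Markov-projected class demand with a multi-type random patch-seeding
    cellular automaton under scenario-specific transition constraints.
    Includes a synthetic landscape generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
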