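Package: shelfbenthos
Title: Layered Benthic Biogeochemistry Model for Shelf-Sea Sediments
Version: 0.1.0
Authors@R:
    person("SSB", "Benthos Developers", email = "benthos@example.org",
           role = c("aut", "cre"))
Description: A desk-scale benthic biogeochemistry model for muddy and sandy
    shelf-sea sites. Tracks benthic organic-matter pools (labile dissolved,
    semi-labile and refractory particulate, buried) with exponential depth
    profiles, a five-group benthic food web (aerobic and anaerobic bacteria,
    meiofauna, deposit and suspension feeders), a three-layer bed nutrient
    scheme (oxic, nitrate-transition, anoxic) with nitrification,
    denitrification, silicate dissolution and phosphate adsorption, and a
    ripple-driven pore-water exchange parameterisation for permeable sands
    that converts tidal bed stress into an advective enhancement of the
    oxic-layer diffusivity. Ships seeded synthetic pelagic forcing, four
    named scenario configurations for a muddy and a sandy site, a first-order
    organic-matter mass-balance box model, and a model-observation comparison
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
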