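Package: benthicflux
Title: Benthic Solute Fluxes from Core Incubations and Pore-Water Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates benthic solute effluxes from long-term closed-core
    sediment incubations with partial overlying-water replacement, computes
    tortuosity-corrected diffusive fluxes from pore-water and microsensor
    depth profiles (Fick's first law), integrates solid-phase inventories,
    and derives simple sediment-water budgets (oxic-zone trapping,
    mixed-layer dilution, sorption release). Includes a synthetic-data
    generator that emulates the three seasonal geochemical regimes of a
    seasonally hypoxic coastal basin (electrogenic sulfur oxidation,
    bioturbation-driven iron cycling, and euxinic conditions) with known
    true fluxes for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
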