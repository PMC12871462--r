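Package: karstCH4
Title: Stable-Isotope Microcosm Simulation and Analysis of Atmospheric
    Methane Oxidation in Karst Cave Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse 13CH4/12CH4 microcosm
    incubations of methane-oxidizing sediments. Generates seeded
    synthetic headspace time series and sediment endpoints with the
    isotopic structure of stable-isotope-probing experiments, estimates
    potential methane oxidation rates from headspace draw-down, fits
    Michaelis-Menten kinetics with aqueous-phase conversion via the
    Bunsen solubility coefficient, runs the 13C mass balance that yields
    carbon-assimilation efficiency and biomass/CO2 partitioning, applies
    the PLFA methylation (FAME) delta-13C correction, and upscales
    oxidation rates to regional methane-sink estimates with Monte-Carlo
    uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
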