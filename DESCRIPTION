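Package: lakescape
Title: Lake-Landscape Gross Primary Production and Its Catchment Drivers
Version: 0.1.0
Authors@R:
    person("Lake", "Metabolism Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating whole-lake gross primary production (GPP)
    and its partitioning between benthic and pelagic habitats (autotrophic
    structuring) in small northern lakes, and for relating those quantities
    to catchment properties.  Includes freshwater carbonate-system
    speciation (CO2 from DIC, pH and temperature; DIC from headspace
    equilibration), light-attenuation fitting from PAR depth profiles,
    hypsographic integration (volumes, depth strata, littoral habitat
    fraction), incubation-based benthic and pelagic GPP estimators with
    lake-average upscaling, terrain analytics (depression filling, D8 flow
    accumulation, catchment delineation, topographic wetness index, land
    cover fractions, hydrology metrics), an inference layer (redundancy
    analysis with supplementary variables, forward-selection multiple
    regression, recursive path analysis with maximum-likelihood fit
    indices), and a seeded synthetic generator of three-biome
    lake-landscape datasets with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
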