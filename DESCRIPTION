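Package: thermopheno
Title: UAV Thermal Phenotyping of Plant Water and Salinity Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to retrieve plant canopy temperature from paired thermal
    infrared and RGB orthomosaics collected by unoccupied aerial vehicles and
    to convert it into water-stress indicators. The package assembles
    drift-corrected thermal mosaics from overlapping swath frames, separates
    vegetation from soil background with the green-red vegetation index and
    an air-temperature ceiling, computes per-plant zonal temperature
    statistics, derives the canopy-air temperature difference and the crop
    water stress index under empirical, theoretical and simplified
    statistical baselines, and compares treated against control cohorts. A
    ground-truthed synthetic scene generator emulating a salinity field
    trial supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
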