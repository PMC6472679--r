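Package: sbcc
Title: Rearing-Success Evaluation for Sea Based Container Culture of European Lobster
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Evaluates the suitability of sea sites for rearing European lobster
    (Homarus gammarus) in moored Sea Based Container Culture (SBCC) systems.
    External hydrodynamic conditions (tidal currents, deep-water wave orbital
    velocities, turbulent fluctuations) and dissolved-oxygen concentrations are
    converted to predicted in-container conditions through linear transfer
    functions with biofouling-coverage modifiers, and scored against behavioural
    flow-velocity limits and an oxygen supply/consumption velocity limit using
    depth-resolved exceedance statistics (percentage of time and longest
    continuous period). Includes a seeded synthetic-data generator emulating
    semidiurnal and spring-neap tidal currents with vertical shear, storm wave
    states, depth-varying turbulence intensity and a seasonal dissolved-oxygen
    cycle, so the full pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
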