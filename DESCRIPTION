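Package: stenoflow
Title: Casson Blood Flow Through Stenosed and Post-Stenotically Dilated Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Closed-form steady-flow hemodynamics of a Casson (yield-stress)
    fluid in an inclined axisymmetric vessel whose wall carries cosine-shaped
    stenoses and post-stenotic dilatations under constant axial body forces
    (magnetization and gravity). Provides the multi-segment wall geometry with
    mild-stenosis validation, the per-station plug-core velocity profile,
    flux/conductance and pressure-gradient inversion, axial integration to
    pressure drop, flow impedance and wall shear stress with their uniform-tube
    normalizations, brute-force numerical oracles guarding every closed form,
    and a deterministic parameter-sweep engine with monotonicity reporting and
    figure reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
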