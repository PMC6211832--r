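Package: meltscreen
Title: Thermal Shift Screening of Membrane Transporters from Melt Curves
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dye-based (CPM) thermal shift assays of
    purified membrane proteins: parsing of plate melt-curve exports and
    sample sheets, apparent melting temperature (Tm) determination as the
    peak of the smoothed first derivative dF/dT with quality control,
    control-subtracted temperature shifts (delta Tm), replicate-level
    significance testing with the conventional star classification,
    hit ranking, and condition contrasts (pH, coupling ions). Includes a
    seeded two-state van't Hoff melt-curve simulator with ligand-coupled
    stabilization and named fixture scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'melt-io.R'
    'simulate.R'
    'scenarios.R'
    'tm-calling.R'
    'screening.R'
    'pipeline.R'
    'meltscreen-package.R'
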