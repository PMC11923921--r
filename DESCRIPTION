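Package: calmapr
Title: Calcium Optical-Mapping Metrics and Bioreactor Process Analytics for
    Cardiomyocyte Aggregate Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for functional characterization of
    cardiomyocyte aggregate and monolayer cultures by calcium-transient
    optical mapping, together with the bioprocess calculations used when
    expanding such cultures in perfused stirred-tank bioreactors.  Provides
    per-pixel and per-trace electrophysiology metrics (dominant frequency,
    inter-beat interval, calcium transient duration at 20/50/70/90 percent
    repolarization, upstroke duration), activation maps and conduction
    velocity by local plane fitting, pacing capture and refractoriness
    accounting, Feret-diameter morphometry of cell aggregates, constant
    power-per-volume agitation scale-up, perfusion mass-balance specific
    metabolic rates, dissolved-oxygen setpoint conversion, and expansion
    factors.  A seeded synthetic-data generator produces fluorescence video
    stacks, aggregate images and perfusion time series with serialized
    ground truth so every stage of the pipeline is testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    deSolve,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
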