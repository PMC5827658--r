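Package: orbvision
Title: Hymenopteran Colour-Vision Contrasts and Foraging Analyses for
    Orb-Weaver Spiders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyses of ontogenetic colour variation and foraging in
    orb-weaver spiders. Implements the trichromatic hymenopteran colour
    hexagon (quantum catch under von Kries background adaptation,
    chromatic and achromatic contrast of body patches against a
    vegetation background), web-geometry and Poisson-GLM foraging-success
    modelling with AIC backward selection and a variance-function-based
    coefficient of determination, maximum-likelihood beta regression for
    frame-web-choice experiments, and seeded synthetic-data generators
    that emulate reflectance spectra, field web observations and choice
    trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    stats,
    utils
Suggests:
    glmmTMB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
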