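Package: diatomflux
Title: Steady-State Carbon-Flux Modeling of Diatom and Phytoplankton Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A coarse-grained, steady-state carbon-flux model of
    nutrient-replete phytoplankton growth across cell sizes. Cellular
    carbon quotas follow empirical allometric power laws, photosynthesis
    is computed by integrating a saturating photosynthesis-irradiance
    response over the intracellular light field of a spherical cell under
    Beer's law (the pigment package effect), and growth rate emerges from
    the balance of carbon fixation against the costs of biosynthesis,
    growth respiration, and silica frustule deposition. Includes
    growth-rate versus volume sweeps per taxon group, fate-of-carbon
    decompositions, sensitivity sweeps, scoring against observed
    growth-volume compilations, and a taxon-normalized transcript-budget
    pipeline with a seeded synthetic metatranscriptome generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
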