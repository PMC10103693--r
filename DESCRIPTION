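Package: cvmbarrier
Title: Cervicovaginal Mucus Barrier Properties from Particle Tracking and
    Vaginal Microbiome Community State Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for studying the barrier function of
    cervicovaginal mucus (CVM) during pregnancy. Implements multiple
    particle tracking microrheology (spot detection, trajectory linking,
    time-averaged mean squared displacement), classification of particles
    into trapped and mobile fractions by a two-component Gaussian mixture
    on log10 MSD with a fixed-cutoff fallback, effective pore-size
    estimation from the hindered diffusion of mucus-penetrating probes via
    an obstruction-scaling model, vaginal microbiome community state type
    (CST) assignment by Bray-Curtis distances and partitioning around
    medoids, and the cohort-level statistics (exclusion rules, 2x2
    relative-risk and odds-ratio tables, Welch t tests, ANOVA with Tukey
    correction, slope regressions) linking CST and demographics to preterm
    birth. Ships synthetic-data generators (Brownian and fractional
    Brownian trajectories, rendered fluorescence video stacks,
    CST-structured taxon compositions, longitudinal cohorts) so the full
    pipeline runs and is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    vegan,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
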