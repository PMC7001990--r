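Package: urbandiet
Title: Scat and Stable-Isotope Diet Analysis Across Urbanization Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carnivore resource use along an
    urban-rural gradient from two complementary data streams: scat
    occurrence records and stable-isotope (d13C/d15N) series measured
    along vibrissae.  Implements occurrence-based diet composition
    indices (frequency and percentage of occurrence, Levins niche
    breadth, Morisita niche overlap), isotope source preparation
    (delta notation, trophic discrimination corrections, source
    pooling, an anthropogenic d13C threshold), a from-scratch Bayesian
    stable-isotope mixing model with MCMC diagnostics, a
    within-individual versus total niche width (WIC/TNW) variance
    decomposition for individual specialization, AIC model comparison
    of land-use covariate models, and seeded synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
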