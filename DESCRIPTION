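Package: sarcomech
Title: Multiscale Analysis of Sarcomere Length Effects on Left-Heart Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive models and analytics for studying how the unloaded
    sarcomere length (Lr) and the zero-active-tension length (L0) shape
    myocardial contraction and global left-heart function. Implements the
    Holzapfel-Ogden passive strain-energy law with closed-form biaxial Cauchy
    stresses, a time-varying-elastance active fiber-stress law with
    length-dependent calcium sensitivity, a 13-scenario Lr/L0 sweep design,
    a reduced closed-loop 0D left-heart surrogate for pressure-volume
    phenotypes, and the downstream analytics: cardiac-function metrics,
    ordinary and piecewise normalized sensitivity analysis, strain
    conversions, deviation scoring against normal ranges, and synthetic-data
    generators with parameter-recovery utilities.
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
    jsonlite,
    withr
Config/testthat/edition: 3
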