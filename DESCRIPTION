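Package: daphniarmor
Title: Biomechanics of Predator-Induced Carapace Defences in Daphnia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the structural mechanics of inducible
    carapace defences in the water flea Daphnia. Provides a small linear
    elasticity finite-element engine (trilinear hexahedra and flat facet
    shells), construction of laminated cylinder-stack models of the Bouligand
    procuticle from microscopy observations, power-law fitting and
    extrapolation of deformation versus lamination, Hertz-model extraction of
    Young's moduli from nano- and micro-indentation force-distance curves with
    critical-force detection, a landmark-based carapace shape pipeline with
    shape-versus-structure swap simulations, the matching statistical tests
    (Mann-Whitney U, pooled t, two-level nested ANOVA), and synthetic-data
    generators with known ground truth so every stage runs without raw
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
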