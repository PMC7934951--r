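Package: angiomsm
Title: Agent-Based Simulation of Filopodia-Mediated Tip Cell Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a constrained memAgent-spring model of endothelial tip
    cell selection during angiogenesis: membrane agents on a cylindrical vessel
    mesh sense a VEGF field, extend and retract stochastic gradient-guided
    filopodia under an actin budget, and compete through delayed Notch-Dll4
    lateral inhibition. Includes a single-cell hysteresis testbed with
    quasi-static external Dll4 ramping for bistability analysis, sensory-map
    active-perception measures (intensity and Shannon entropy with Laplace
    smoothing), salt-and-pepper pattern scoring, and Lomb-Scargle spatial
    periodogram analysis of one-dimensional intensity profiles with a synthetic
    periodic-profile generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
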