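Package: phytotherm
Title: Thermal Reaction Norms, Q10 Dependencies and Warming Projections
    for Marine Phytoplankton Functional Types
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits unimodal (Norberg-type) thermal reaction norms to
    strain-level phytoplankton growth measurements and derives thermal
    traits (optimum, limits, performance breadth, curve skewness).
    Estimates functional-type maximum-growth temperature dependencies by
    exact 99th-quantile exponential regression with Markov chain marginal
    bootstrap confidence intervals, yielding per-group temperature
    coefficients (Q10) and activation energies.  Computes static
    thermal-capacity metrics against baseline habitat temperatures --
    thermal safety margin, warming tolerance, and the distance to growth
    equivalence -- and projects proportional growth change and range
    shifts between two gridded sea-surface-temperature epochs under a
    20 percent viability rule.  Includes a synthetic-data module that
    emulates both the strain compilation and zonally structured SST
    fields so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
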