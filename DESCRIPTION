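Package: assorthr
Title: Hamilton's Rule in Assortatively Structured Group Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the evolution of cooperation in populations
    that interact in groups of equal size under assortative group formation.
    Represents fitness functions for cooperators and defectors together with
    population structures (families of group-composition distributions indexed
    by the overall cooperator frequency), extracts the population structure
    profiles experienced by rare mutants, and evaluates the direction of
    selection exactly. Computes costs, benefits and relatedness under both the
    counterfactual and the regression (partial least-squares) definitions of
    Hamilton's rule, locates equilibria, classifies systems by synergy
    conditions, maps regions where inclusive fitness disagrees with the
    direction of selection, and simulates the sampling mechanisms that produce
    spurious violations in empirical data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
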