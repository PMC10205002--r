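Package: glandcov
Title: Protein-Lipid Covariation Analysis of Lizard Femoral-Gland Secretions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetically-informed covariation analysis between
    the protein and lipid fractions of lizard femoral-gland secretions.
    Implements electrophoretic-profile complexity statistics (peak richness
    and Shannon entropy), centred-log-ratio compositional transforms with
    multiplicative zero replacement, phylogenetic two-block partial least
    squares under a Brownian-motion model with permutation significance,
    phylogenetic generalized least squares with marginal (type III) sums of
    squares tested by residual randomization (RRPP), prediction of profiles
    along a lipid gradient with localization of responsive molecular-weight
    regions, and a synthetic-data generator with known ground truth so the
    whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
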