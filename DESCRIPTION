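Package: molarwear
Title: Occlusal Fingerprint Analysis of Molar Macrowear
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mesh-based measurement of dental macrowear on lower molars and the
    statistics used to compare wear patterns between groups of individuals.
    Implements static occlusal fingerprint analysis (wear-facet areas grouped by
    power-stroke phase, facet dip angles against the cervical reference plane,
    and the occlusal relief index), a timestep collision simulation of the
    masticatory power stroke between antagonist tooth meshes, compositional
    statistics on (buccal phase I, lingual phase I, phase II) facet-area
    proportions (isometric log-ratio transform, compositional centers, ternary
    coordinates, PERMANOVA, homogeneity-of-dispersion test, Welch t-tests with
    effect sizes), and generators for synthetic crown meshes, antagonist pairs
    and cohort tables so the whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
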