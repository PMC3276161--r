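Package: msatrare
Title: Mutation Rarefaction and Quality Control for Microsatellite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing microsatellite (short tandem repeat)
    diversity across marker classes with different mutation rates.
    Implements fragment-length quality control (inference of repeat-unit
    length and offset, consistency filtering, conversion to repeat
    counts), a mutation-rarefaction transform that rescales pairwise
    repeat-difference distributions and heterozygosities to a common
    reference mutation rate under the stepwise mutation model, estimation
    of relative mutation rates between marker classes, sample-size-aware
    heterozygosity and pairwise F[ST] matrices, bootstrap regression of
    diversity on a population covariate, and a coalescent stepwise-mutation
    simulator for generating multi-population test panels with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
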