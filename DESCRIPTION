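Package: iatropath
Title: Measuring and Comparing Staged Medical Interventions in Childbirth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the intensity of medical intervention
    during labour and for comparing it between cohorts.  Intervention
    histories are represented as binary paths through an ordered sequential
    protocol (by default augmentation, ventouse, caesarean section); from
    path-count tables the package computes the overall treatment ratio and
    iatrogenic labour index in five equivalent forms, estimates forward
    progression proportions under an absorbing Markov representation of
    labour, decomposes inter-cohort differences by stepwise replacement of
    progression proportions and by a multiplicative treated-proportion split,
    produces standard Robson ten-group reports with direct standardization,
    tests path distributions and individual ratios between cohorts, and
    simulates seeded synthetic cohorts (including controlled violations of
    the Markov property) for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
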