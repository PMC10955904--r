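Package: excisionforce
Title: Generative Force Modelling of Elliptical Excision for Surgical Skill Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing scalpel incision-force recordings from
    elliptical excision tasks. Implements a Maxwell viscoelastic model of
    tool-tissue interaction (force/displacement transforms and forward force
    simulation), a two-regime Gaussian hidden Markov model of virtual blade
    velocity fitted by expectation-maximization, a seeded synthetic-cohort
    generator for archetypal cutting behaviours, PCA-based skill features
    (abruptness, energy, confidence) over fitted model parameters, and the
    accompanying statistical toolkit: Levene variance test, Welch ANOVA with
    Games-Howell post-hoc comparisons, Spearman correlation with permutation
    critical values, and intraclass correlation ICC(2,1).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
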