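Package: corticowalk
Title: Force-Based Simulation and Quantification of Radial Cortical Neuron Migration
Version: 0.2.0
Authors@R:
    person("Corticowalk", "Maintainers", email = "maintainers@corticowalk.dev", role = c("aut", "cre"))
Description: Tools for studying radial migration of cortical projection
    neurons in the developing neocortex. Provides a 2D force-based biased
    persistent-random-walk migration simulator with tissue-resistance
    compartments and a mixed control/mutant population model, trajectory
    statistics for tracked neurons (total/net distance, mean straight-line
    speed, meandering index, zone occupancy), laminar-position
    quantification of marked neurons between tissue boundaries with
    ten-zone binning and arcsine/ANOVA comparison statistics, dense
    optical-flow based correction of non-linear tissue drift in time-lapse
    movies, and synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
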