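Package: clocknet
Title: Circadian Clock Regulatory Networks, CTL Model Checking and Timed
    Continuous Petri Net Simulation of Jet Lag
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic-logic (Thomas) modeling of the mammalian circadian
    clock coupled to the cell-cycle regulators MYC and p53. Builds
    asynchronous state graphs of boolean regulatory networks, infers
    logical K-parameters by explicit-state CTL model checking against
    temporal-logic encodings of biological observations, converts the
    selected logical model into a timed continuous Petri net with
    complementary places and a delayed gate subnet, and simulates normal,
    mild and chronic jet-lag scenarios, reporting oscillation periods,
    peak phases, p53 suppression and MYC persistence orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
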