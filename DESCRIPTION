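Package: aclthresh
Title: Frontal-Plane Torque-Balance Thresholds for Non-Contact ACL Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a frontal-plane torque-balance model of the knee
    during single-leg landing with an extended knee. The vertical ground
    reaction force generates an abduction torque about the lateral femoral
    condyle which is resisted by the anterior cruciate and medial collateral
    ligaments, the quadriceps via the patellar tendon, the semitendinosus
    group, and bodyweight acting at the centre of gravity. The package
    solves the abduction-adduction balance for the critical ground reaction
    force as a function of shin angle (the angle-of-damage curve), extends
    the model with a Coulomb shoe-surface friction coefficient and partial
    muscle activation fractions, and propagates anthropometric variability
    through the threshold via Monte Carlo over synthetic cohorts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
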