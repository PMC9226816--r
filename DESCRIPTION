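Package: apratedep
Title: Rate-Dependent Action Potential Prolongation by Potassium Channel Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell simulation and analysis of rate-dependent action
    potential duration (APD) prolongation in the human ventricular epicardial
    myocyte. Implements the ten Tusscher-Panfilov (2006) epicardial ionic model
    with scalable maximal conductances for the slow delayed rectifier (IKs),
    rapid delayed rectifier (IKr) and inward rectifier (IK1) potassium currents;
    steady-state pacing and restitution protocols; action potential phase
    segmentation and shape features (APA, APD90, phase-average ionic currents
    via the membrane slope identity, triangulation and area indices);
    repolarization-reserve estimation by constant depolarizing current
    injection; rate-dependence statistics classifying interventions as reverse
    or positive rate dependent; and a particle swarm optimizer that searches
    conductance-multiplier combinations prolonging APD with maximal positive
    rate dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
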