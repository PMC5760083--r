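Package: emdadapt
Title: Adaptive Elementary Motion Detector Arrays for Insect Motion Vision
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the adaptive visual motion pathway of flying insects:
    adaptive photoreceptors, large monopolar cells with ON/OFF half-wave
    rectification, correlation-type elementary motion detectors (EMDs) with
    slow divisive motion adaptation and an activity-dependent Lipetz exponent,
    and a lobula plate tangential cell (LPTC) that linearly pools the detector
    array. Includes generators for the benchmark sine-grating protocols
    (velocity-transient trains, direction-specific adaptation, contrast-gain
    sweeps), procedural 3D worlds (cloud-textured corridor and decagonal arena
    with saccadic flight dynamics) rendered onto a spherical eye by ray
    casting, and the response-contrast statistics used to quantify how motion
    adaptation enhances the representation of nearby objects in optic flow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
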