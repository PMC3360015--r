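Package: bimanrehab
Title: Simulating Motor-Cortex Reorganization under Unimanual and Bimanual
    Stroke Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computational model of post-stroke motor-cortex
    reorganization built on cosine-tuned neurons and population-vector
    decoding. A directional lesion depletes neurons whose preferred
    directions (PDs) fall in a wedge; trial-by-trial supervised
    (angular-error) and unsupervised (metabolic) gradient learning then
    reorganizes the surviving population. Movement-condition variants --
    quenched or annealed rotations of the encoding PDs, modulation-depth
    changes, joint encoding-and-decoding rotations, and an analytic
    inter-hemispheric-inhibition derivation of effective rotations --
    let the user test which features of bimanual movement drive
    reorganization. Includes reorganization metrics (circular histograms,
    entropy-based uniformity, lesion-wedge fill), scripted experiment
    scenarios, a YAML-configured command-line interface, and fixture
    generators for reproducible simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
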