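Package: orthofem
Title: Finite-Element Prediction of Orthodontic Tooth Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating orthodontic canine retraction with a
    small-strain linear-elastic tetrahedral finite-element model and for
    calibrating and validating a quadratic law that links periodontal
    ligament stress under a 1 N retraction force to monthly clinical tooth
    movement. Includes a parametric generator for canine/PDL/alveolar-bone
    anatomy (with STL export), a region-tagged tetrahedral mesher with VTK
    and Abaqus-style export, stress sampling at canine root landmarks,
    rigid best-fit superimposition (Kabsch), Dahlberg method error, and an
    end-to-end multi-period retraction study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
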