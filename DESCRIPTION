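Package: osteotherm
Title: Inferring Thermophysiology of Extinct Tetrapods from Bone
    Vascular Canal Diameters
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for inferring endothermy versus ectothermy in fossil
    tetrapods from quantitative osteohistology. Computes the harmonic mean of
    primary vascular canal diameters per thin section, converts it to a
    probability of endothermy through a published phylogenetic-logistic
    calibration, classifies specimens against a probability cut-off,
    stochastically time-scales a cladogram from stratigraphic ranges under the
    'equal' and minimum-branch-length ('mbl') algorithms, and performs
    maximum-likelihood marginal ancestral-state reconstruction of the binary
    thermophysiology character under the Mk model, aggregated over tree
    ensembles. Includes a birth-death simulator of fossil-bearing trees,
    characters, stratigraphic ranges and canal measurements for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
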