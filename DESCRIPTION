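Package: platebend
Title: Internal Bending Loads on Phalangeal Fracture-Fixation Plates from
    Image-Based Finite Element Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for determining the internal bending
    moment acting on a plate osteosynthesis of a phalangeal fracture.
    Synthetic CT-like phantom volumes of an osteotomized phalanx are
    segmented, rigidly co-registered with a normalized mutual information
    metric, and converted to specimen-specific quadratic tetrahedral
    finite element models with density-derived bone moduli.  Optical
    marker trajectories are reduced to divot-referenced rigid fragment
    transforms that drive the model in evenly spaced displacement steps,
    and the bending moment is extracted at a mid-plate cut plane that
    follows the deformed centerline.  Includes PEEK material calibration
    from dog-bone tension curves, a flexural capacity check for moldable
    composite fixation patches, and summary statistics across specimens
    and digits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
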