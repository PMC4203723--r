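Package: stretchFRET
Title: Calcium Oscillation and Substrate Strain Analysis for FRET Imaging
    Under Mechanical Stretch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric FRET calcium imaging of cells
    on elastic substrates subjected to prolonged mechanical stretch.
    Provides synthetic generators for two-channel (donor/FRET) time-lapse
    stacks with known calcium-transient ground truth and for fiducial-bead
    fields deformed by a tip-pull displacement model; ratiometric emission
    ratio computation and ROI trace extraction; peak-based oscillation
    metrics (frequency per minute, mean peak amplitude, responder fraction,
    loading-segment comparison); bead matching, displacement-field
    interpolation, small-strain and stress mapping of the substrate; and
    the group-comparison statistics used in mechanobiology studies
    (Student's t-test, Bonferroni multiple comparison of means at 95%
    confidence).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'ratiometric.R'
    'io.R'
    'mechanics.R'
    'oscillometry.R'
    'plot-methods.R'
    'stats-compare.R'
    'stretchFRET-package.R'
    'synthgen-beads.R'
    'synthgen-trace.R'
    'synthgen-stack.R'
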