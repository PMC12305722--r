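Package: gimbalScan
Title: Simulated Gimbal-Gantry Ultrasound Scanning and Optimal Tumor-Slice Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully simulated gimbal-gantry ultrasound acquisition system for
    optimal tumor-slice selection. Provides a digital breast-phantom generator
    with ellipsoidal lesions and ground-truth labels, a B-mode slice
    synthesizer (oblique trilinear resampling, depth attenuation, Rayleigh
    speckle, log compression), a 3-DOF probe pose model (linear rail plus
    gimbal pitch/roll) with stepper/servo motor-command emulation, an
    area-fraction tumor-presence scorer with occlusion saliency and Dice/IoU
    validation, and the two-level scan-search procedure (zigzag angular sweep
    per station, coarse-to-fine linear refinement) together with an
    exhaustive-search oracle, linear-versus-angular comparison and coverage
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bmode.R'
    'coverage.R'
    'experiment.R'
    'geometry.R'
    'gimbalScan-package.R'
    'phantom.R'
    'scoring.R'
    'search.R'
    'utils.R'
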