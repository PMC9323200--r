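Package: cedphantom
Title: Bench-Side Calibration of Agar Phantoms for Convection-Enhanced
    Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative bench-side modelling of convection-enhanced
    delivery (CED) infusions. Segments dye boluses from time-lapse
    photographs of transparent agar phantoms and converts them to
    distribution volumes under an ellipsoidal model, extracts contrast
    bolus volumes from T1-weighted MRI scans by seeded threshold
    shrink-wrapping, and calibrates the phantom against in vivo infusion
    trajectories with through-origin random-slope mixed models,
    diffusion-time matching and pooled t-tests. Includes stair-step
    infusion protocol schedules and a synthetic-data generator with known
    ground truth for end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    lme4,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
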