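Package: vertfe
Title: Vertebral Strength from CT by Voxel-Based Finite Element Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts vertebral compressive strength from CT-like image
    volumes by the quantitative-CT finite element route: Hounsfield units
    are mapped to apparent and ash density and on to transversely
    isotropic elastic moduli and principal-stress strength limits; the
    labelled vertebra is meshed into linear tetrahedra on a structured
    grid; a displacement-controlled compression with progressive element
    damage yields the force-displacement curve whose peak is the failure
    load. Ships a synthetic vertebra phantom generator (cortical shell,
    correlated trabecular field, posterior elements, contrast enhancement,
    slice-thickness resampling, paired cohorts) so that the effects of
    scan conditions and cohort strength differences can be studied without
    patient data, together with the agreement statistics used in such
    studies (R-squared, Bland-Altman limits, RMSCV, t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
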