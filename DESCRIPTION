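Package: condylometry
Title: Condylar Head Volumetry and Cephalometric Pattern Analysis for
    CBCT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies mandibular condylar head volume from voxel volumes
    in Hounsfield units using a landmark-constructed cut plane parallel to
    the Frankfurt plane through the pterygoid fovea, computes the three
    cephalometric angles used to classify sagittal and vertical skeletal
    patterns (ANB, intermaxillary divergence, total gonial angle), and runs
    the associated two-level statistics: random-intercept linear regression
    fitted by REML with Wald intervals, absolute-agreement single-measure
    intraclass correlation ICC(A,1), and two-sample power via the
    noncentral t distribution. Ships synthetic voxel phantoms with analytic
    ground-truth volumes and cohort simulators with the corresponding
    two-condyles-per-subject variance structure, plus an end-to-end study
    pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
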