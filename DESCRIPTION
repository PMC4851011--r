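Package: VesselTrace
Title: Vascular Segment Identification in Intraoperative 3D
    Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies a user-selected vascular segment from a
    preoperative contrast-enhanced T1 MR volume inside intraoperative 3D
    contrast-enhanced ultrasound volumes acquired before and after brain
    tumor resection. Vessels are enhanced with a multiscale Hessian
    (Sato) vesselness filter and extracted by Otsu thresholding; the
    segment is then located by ROI-constrained rigid registration under
    one of three similarity measures (normalized cross correlation,
    normalized mutual information, normalized gradient fields) and the
    result is evaluated with Dice and Hausdorff metrics. A synthetic
    tube-phantom generator with known ground truth supports validation
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'transforms.R'
    'volume-io.R'
    'volume-ops.R'
    'vesselness.R'
    'segmentation.R'
    'similarity.R'
    'registration.R'
    'pipeline.R'
    'metrics.R'
    'phantoms.R'
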