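Package: beefscan
Title: Automatic Beef Quality Measurement from Carcass and Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic estimation of beef quality parameters from
    images. Segments the rib eye (longissimus dorsi cross-section) on color
    carcass images with a three-stage distance-regularized level-set curve
    evolution and reports its area; measures the subcutaneous backfat
    thickness profile by evolving the meat convex hull along its normals to
    the steak boundary; and estimates the intramuscular fat percentage (IMF%)
    from B-mode ultrasound regions of interest via a 42-dimensional texture
    descriptor, principal component reduction and support vector regression.
    Includes ground-truthed steak and ultrasound phantom generators for
    validation, the evaluation metrics (relative area error, concordance,
    RMSE/R-squared) and a repeated split protocol, plus a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'preproc.R'
    'levelset.R'
    'backfat.R'
    'usroi.R'
    'features.R'
    'imf.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
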