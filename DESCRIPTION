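Package: irtasym
Title: Thermal Asymmetry Analysis of Facial Infrared Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated analysis of facial and mouth-cavity infrared
    thermograms for screening of orofacial/maxillofacial thermal
    abnormality. Estimates the facial symmetry axis from gradient-based
    edge detection, a convex hull of the edge points and a direct
    least-squares ellipse fit; splits the analysis field into left and
    right temperature collections; extracts eight left-right asymmetry
    features (mean, maximum and mean-absolute-deviation differences plus
    histogram exceedance counts for the face and the open mouth cavity);
    and classifies patients into non-tumor versus tumor classes with a
    1-nearest-neighbor classifier evaluated by repeated train/test
    splits, confusion-matrix metrics and ROC/AUC. Includes a synthetic
    phantom generator with known symmetry axis and lesion ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
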