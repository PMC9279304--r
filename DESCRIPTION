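Package: cbctseg
Title: Coarse-to-Fine 3D Segmentation of Craniomaxillofacial CBCT and
    Pharyngeal Airway Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage (coarse-to-fine) 3D U-Net semantic segmentation of
    cone-beam computed tomography (CBCT) head volumes into background, upper
    skull, mandible, maxillary teeth, mandibular teeth and airway; pharyngeal
    airway morphometry (volume in cc, per-slice cross-sectional area in mm^2,
    narrowest point in mm) with STL surface export; and method-agreement
    statistics (two-way mixed-model intraclass correlation, Mann-Whitney U,
    Kruskal-Wallis H). Includes a synthetic CBCT head-phantom generator so the
    whole pipeline is exercisable without patient data, NIfTI and DICOM-series
    volume IO, spacing-aware trilinear/nearest resampling, patch-queue
    training with a one-cycle learning-rate schedule, leakage-free coarse-hint
    generation via k-fold cross-validation, and overlapping-patch inference
    with centre-weighted aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
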