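Package: octopam
Title: Hybrid Optoacoustic Mesoscopy and OCT Capsule Endoscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid optoacoustic-mesoscopy (OPAM) and
    optical-coherence-tomography (OCT) tethered-capsule scans of oesophageal
    mucosa, with an emphasis on Barrett's oesophagus. Provides a digital
    tissue-phantom generator for six mucosal types (normal squamous mucosa,
    gastric metaplasia types 1 and 2, intestinal metaplasia, dysplasia,
    intramucosal cancer) and a helical capsule-scan simulator; frequency-band
    optoacoustic reconstruction (band-pass filtering plus analytic-signal
    envelope); OPAM/OCT axial co-registration on a mesh calibration target;
    marker-based frame alignment, depth-range en-face projections, depth-coded
    vascular rendering and cylindrical-to-Cartesian unwrapping; quantification
    of the five region-of-interest features used to grade Barrett's mucosa
    (epithelial inhomogeneity, vascular density, vascular depth, OCT
    penetration depth, gland transparency); a two-stage rule-based mucosal-type
    classifier; and the supporting statistics (Wilcoxon rank-sum, empirical
    ROC/AUC, Krippendorff's alpha, classification metrics, imaging metrology).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    signal,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
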