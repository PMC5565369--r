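Package: filodyn
Title: Quantitative Analysis of Signalling Filopodia (Cytoneme) Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the dynamics of signalling filopodia
    (cytonemes) from manually tracked base/tip coordinates, as produced by
    the MTrackJ plugin of ImageJ/Fiji.  Computes per-frame filopodium
    extent, fits two-phase "triangle" (elongation/retraction) and
    three-phase "trapezoid" (elongation/stationary/retraction)
    piecewise-linear kinetic models, extracts maximum extent, lifetime and
    elongation/retraction velocities, classifies each filopodium by model
    fit, and compares cohorts with Shapiro-Wilk and Mann-Whitney-Wilcoxon
    statistics.  Also quantifies wing-disc cytoneme lengths (mean of the
    ten longest protrusions) and morphogen-gradient domain widths from 1D
    intensity profiles along the anterior/posterior axis.  A synthetic
    track and intensity-profile generator with recorded ground truth makes
    the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
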