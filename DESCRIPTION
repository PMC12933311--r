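Package: ivoctreg
Title: Automated Co-Registration of Intravascular Ultrasound and Optical
    Coherence Tomography Pullbacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Longitudinal and circumferential co-registration of paired
    intravascular ultrasound (IVUS) and optical coherence tomography (OCT)
    coronary pullbacks from per-frame annotations (lumen contours, side-branch
    bounding boxes, calcium arcs). Frames are matched longitudinally by
    dynamic time warping over smoothed geometric feature sequences, and the
    rotational orientation of OCT relative to IVUS is estimated at anatomical
    landmark pairs by feature-weighted normalized cross-correlation of
    circular profiles with a shape-regularized dynamic-programming path,
    then interpolated circularly to all frames. Includes a phantom pullback
    simulator with known ground-truth correspondence and rotation, an
    observer-agreement evaluation suite (Lin's concordance correlation,
    Spearman correlation, Williams Index with jackknife confidence interval,
    Bland-Altman limits, Wilcoxon signed-rank test), JSON/CSV file formats,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
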