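Package: mcindex
Title: Macular Curvature Index from OCT Radial B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies posterior eye-wall curvature from optical coherence
    tomography (OCT) radial B-scans for posterior staphyloma screening.
    Detects or ingests the retinal pigment epithelium (RPE) segmentation
    line, computes a sliding three-point arc radius along the line in
    physical (mm) coordinates, extracts each scan's minimum radius r,
    averages r over an eye's radial scan set to R, and reports the macular
    curvature index MC = 337.5/R with a classification against the MC-40
    (8.44 mm radius) reference. Includes a synthetic ocular phantom
    generator (spherical posterior pole with an optional Gaussian
    outpouching of known analytic apex curvature) so every pipeline stage
    can be validated against closed-form ground truth, and a batch
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
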