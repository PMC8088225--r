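Package: vitreoct
Title: Quantification of Anterior Vitreous Opacification in 3-D SS-OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the retrolental (anterior)
    vitreous in volumetric swept-source optical coherence tomography (SS-OCT)
    scans. Provides eye-motion correction (axial correction from a paraboloid
    fit to the delineated posterior lens capsule; transverse correction from
    pupil circularity), segmentation of the crystalline lens and a 2-mm
    retrolental vitreous slab, the opacification indices VOD, LOD and VOR,
    depth-coded maximum intensity projections, the area under the log-log
    contrast sensitivity function (AULCSF), and the accompanying statistical
    layer (one-way random-effects ICC, Pearson correlation with Fisher
    confidence intervals, LOESS comparison, normality-gated group tests,
    Tukey ladder of powers, forward stepwise regression). A synthetic phantom
    and cohort generator with full ground truth makes every stage testable
    without access to raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    EBImage,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
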