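Package: gaitagree
Title: Reliability and Agreement Analysis of 2D Video-Based Sagittal Gait
    Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how reliably sagittal-plane hip, knee and
    ankle angles at initial contact can be measured from 2D video with a
    standard lower-limb marker set, and how well such measurements agree
    with a 3D optical reference system. Implements the marker-based joint
    angle constructions, gait event detection from vertical ground reaction
    force (20 N threshold) and heel kinematics, intraclass correlation
    coefficients (single measures, absolute agreement and consistency) with
    F-based confidence intervals, Bland-Altman limits of agreement, paired
    t comparisons, and the Walter-Eliasziw-Donner sample-size formula for
    reliability studies. A synthetic cohort generator with an explicit
    observer/session/system error structure (marker re-placement, frame
    selection, digitization jitter, perspective projection) makes the whole
    pipeline testable end to end without raw motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
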