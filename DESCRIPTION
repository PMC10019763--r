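Package: nematicdefects
Title: Topological Defect Analysis for Active Nematic Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell monolayers that behave as active
    nematics: estimates the director field from textured microscopy images
    by the gradient structure tensor, detects +1/2 and -1/2 topological
    defects from minima of a windowed nematic order parameter, measures
    defect charge and axis orientation by winding along virtual loops,
    computes velocity fields by window cross-correlation PIV, links defects
    into tracks and classifies them as stationary or motile, averages
    director and velocity fields in a defect-centered frame (axial velocity
    profiles, contractility sign, cell-density accumulation at the defect
    head), and quantifies focal-adhesion morphometrics (area, circularity,
    orientation) in the head versus tail regions of a defect. A synthetic
    scene generator provides ground-truth director fields, textures, flow
    fields, trajectories, focal-adhesion images and nuclei point sets so
    every stage is verifiable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
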