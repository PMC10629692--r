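Package: flyhull
Title: Hull Reconstruction-Reprojection Pose Estimation for Free-Flying Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free extraction of body and wing kinematics of free-flying
    fruit flies from synchronized multi-camera silhouette videos. Implements
    visual-hull voxel carving with part-specific expanded hulls that resolve
    wing-body and wing-wing occlusions, reprojection-based recovery of
    occluded wing pixels, leading/trailing-edge hull reconstruction, per-wing
    Euler angles relative to the stroke plane, spanwise wing-deformation
    profiles, body angular rates, and a camera-configuration visibility
    analysis. Ships a synthetic articulated-fly renderer with prescribed
    wingbeat kinematics so every stage is testable against ground truth
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
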