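Package: leafnurbs
Title: Parametric NURBS Surface Modelling of Single-Leaf Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a smooth parametric surface model from a 3D point
    cloud of a single plant leaf. The pipeline standardizes the cloud pose by
    principal component analysis, slices it along the leaf axis, extracts a
    point set to be fitted (an ordered grid or unordered per-slice columns),
    fits a B-spline surface by per-column/per-row curve approximation with
    element-wise averaged knot vectors, and optionally converts the result to
    rational (NURBS) form by optimizing control-point weights with particle
    swarm optimization. Accuracy is measured by Euclidean point-to-surface
    distances obtained with Newton point inversion (RMSE, maximum distance,
    and their convex combination). Includes readers/writers for PLY, XYZ/CSV
    and OBJ point clouds, a voxel-grid downsampling filter, and a synthetic
    leaf generator with known ground-truth surfaces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
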