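Package: palate3D
Title: 3D Reconstruction of Embryonic Palate and Tongue from Serial
    Histological Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional surface models of the embryonic
    oral cavity (palatal shelves and tongue) from ordered stacks of
    brightfield H&E section photographs. The pipeline converts each RGB
    section to greyscale via the green channel, denoises with a square mean
    filter, thresholds to a binary mask, selects the largest 8-connected
    bright component as the oral cavity, rigidly aligns the slice masks to a
    common reference, assembles them into an anisotropic labeled voxel
    volume with volume measurement, and extracts cleaned, smoothed triangle
    meshes exportable to STL and PLY. A synthetic phantom generator renders
    serial-section stacks of exactly known 3D geometry (tongue body and two
    lateral shelf silhouettes inside a bright cavity, with per-slice rigid
    jitter and imaging noise) so every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
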