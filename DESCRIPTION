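Package: polartissue
Title: Boundary-Induced Polar Order in Confined Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing boundary-induced polar ordering in confined
    epithelial tissues such as the early post-implantation mouse epiblast.
    Provides a finite-element minimizer of a confined polar-fluid free energy
    on axisymmetric two-spherical-cap domains with heterogeneous surface
    anchoring (tangential on one cap, perpendicular on the other), including
    topological-defect detection and phase diagrams; a 3D cell-orientation
    quantification pipeline that turns segmented label volumes into per-cell
    shape anisotropy, polarity vectors, boundary normals and angles; a
    rotationally averaged, elongation-weighted nematic (Q-tensor) field with
    director and strength maps; grid-search estimation of the tissue's
    correlation and anchoring lengths from measured alignment fields; and a
    seed-deterministic synthetic-embryo generator used to exercise the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
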