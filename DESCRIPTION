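Package: phenopou
Title: Acquisition Planning and Geometric Accuracy Evaluation for
    Structure-from-Motion Plant Phenotyping Point Clouds
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planning nadir-view image acquisition for
    structure-from-motion (SfM) reconstruction of greenhouse scenes and for
    evaluating the geometric accuracy of dimension measurements taken from
    the resulting dense point clouds.  Implements the field-of-view, image
    overlap, spatial resolution and power-of-unit (POU) survey geometry
    relations; robust trimmed-histogram extraction of object height and
    per-slice x/y dimensions from point clouds of calibration objects;
    a triangular greenness index (TGI) plus k-means pipeline for plant
    height measurement from colored clouds; power-law regression of
    measurement error against POU, agreement statistics and one-way ANOVA;
    and a seeded synthetic-scene generator that emulates SfM dense clouds
    of cuboid, cylinder and mushroom-shaped calibration objects and of
    green-canopy plants on a dark bed, with POU-dependent degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
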