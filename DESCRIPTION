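Package: wovencell
Title: Unit-Cell Fiber Volume, Porosity and Stiffness Models for 3D Woven
    Scaffold Preforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for three-dimensional woven polyglycolic acid
    (PGA) fiber preforms used as tissue-engineering scaffolds. Reduces raw
    preform measurements (structure dimensions, uncrimped yarn lengths,
    directional masses, bulk density) to yarn crimp ratios and directional
    fiber-volume and porosity fractions; evaluates closed-form unit-cell
    models of the plain, semi-interlaced and orthogonal 3D weave
    architectures; cross-checks them with a voxelized numerical unit cell;
    and predicts scaffold stiffness, shear modulus, Poisson ratio and
    tensile strength by the rule of mixtures for fiber/hydrogel composites.
    Includes a synthetic measurement generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
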