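Package: valvegeom
Title: Parametric Geometric Modelling of Semilunar Heart Valve Cusps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric geometry of the fully open human pulmonary valve,
    modelling each cusp as one third of a cylindrical shell bounded above by
    a sine free edge. Provides the cusp parameterization (cylinder radius
    derived from cusp width, sine boundary in flattened and angular
    coordinates), least-squares fitting of the free-edge curve to measured
    boundary points, derived anatomical measurements (annulus diameter and
    circumference, cusp area in closed form and by surface quadrature, total
    valve and orifice areas), triangulated surface meshes of single cusps and
    the assembled three-cusp valve with export to STL, OBJ, PLY and legacy
    VTK, synthetic morphometric cohort generation from published per-cusp
    width and height statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
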