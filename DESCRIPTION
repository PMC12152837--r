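Package: micellar
Title: Small-Angle Scattering and Spectroscopic Analysis of Lipopeptide Micelles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of lipopeptide self-assembly into charged
    micelles. Provides closed-form small-angle X-ray scattering (SAXS) form
    factors (homogeneous sphere, core-shell sphere, Gaussian chain, mass-fractal
    power law), the Percus-Yevick hard-sphere and Hayter-Penfold rescaled-MSA
    charged-sphere structure factors, weighted nonlinear model fitting with a
    classed fit object, model-independent micelle molar mass and association
    number from absolute-scale forward scattering, circular dichroism
    helix-fraction quantification, radial electron-density and
    solvent-accessible surface area profiling of micelle coordinate sets,
    critical micelle concentration breakpoint estimation, transepithelial
    electrical resistance arithmetic, and seeded synthetic-data generators for
    every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    lhs,
    signal,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
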