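Package: flexmode
Title: Elastic-Network Normal-Mode Flexible Fitting into Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible refinement of atomic protein models (e.g. AlphaFold2
    predictions) against cryo-EM density maps using the low-frequency normal
    modes of a C-alpha elastic network model as basis functions for
    displacement. Builds and diagonalizes the Hookean-spring Hessian of a
    C-alpha network, extends the resulting mode displacement fields to all
    atoms, simulates density maps from deformed models at a stated resolution
    by Gaussian kernel deposition, and optimizes a mode-elongation vector so
    that the simulated map maximizes its correlation (Pearson or unnormalized
    inner product) with the target map, using derivative-free local (Powell,
    Nelder-Mead) or global (dual annealing, differential evolution)
    optimization. Includes MRC2014 and Situs ASCII map input/output, zone
    masking and zero-padding utilities, and a synthetic fixture generator with
    known ground-truth deformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
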